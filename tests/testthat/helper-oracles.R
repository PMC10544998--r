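## Independent scalar-loop oracle implementations of every loss and of the
## confusion-matrix metrics. Deliberately written with plain for-loops and
## no vectorized/array shortcuts so they share no code path with the
## package implementations they check.

oracleSoftmax <- function(z, temperature) {
    n <- length(z)
    m <- z[1] / temperature
    for (i in seq_len(n)) m <- max(m, z[i] / temperature)
    s <- 0
    for (i in seq_len(n)) s <- s + exp(z[i] / temperature - m)
    p <- numeric(n)
    for (i in seq_len(n)) p[i] <- exp(z[i] / temperature - m) / s
    p
}

oracleSoftTarget <- function(zs, zt, temperature) {
    total <- 0
    for (r in seq_len(nrow(zs))) {
        ps <- oracleSoftmax(zs[r, ], temperature)
        pt <- oracleSoftmax(zt[r, ], temperature)
        for (i in seq_along(ps)) total <- total - pt[i] * log(ps[i])
    }
    total / nrow(zs)
}

oracleFocal <- function(probs, labels, gamma, weights) {
    total <- 0
    for (r in seq_len(nrow(probs))) {
        p <- probs[r, labels[r]]
        if (p < 1e-12) p <- 1e-12
        total <- total - weights[labels[r]] * (1 - p)^gamma * log(p)
    }
    total / nrow(probs)
}

## equal spatial sizes only (the no-resize path)
oracleFeatureMatch <- function(sfeats, tfeats, adapterList) {
    stageSum <- 0
    for (k in 1:4) {
        s <- sfeats[[k]]; t <- tfeats[[k]]
        A <- adapterList[[k]]$W; b <- adapterList[[k]]$b
        ds <- dim(s); dt <- dim(t)
        sq <- 0
        for (n in seq_len(dt[4])) for (h in seq_len(dt[2]))
            for (w in seq_len(dt[3])) for (co in seq_len(dt[1])) {
                acc <- b[co]
                for (ci in seq_len(ds[1]))
                    acc <- acc + A[co, ci] * s[ci, h, w, n]
                sq <- sq + (acc - t[co, h, w, n])^2
            }
        stageSum <- stageSum + sq / prod(dt)
    }
    stageSum / 4
}

oracleMetrics <- function(counts) {
    C <- nrow(counts)
    prec <- numeric(C); rec <- numeric(C); f1 <- numeric(C)
    total <- 0; correct <- 0
    for (i in seq_len(C)) for (j in seq_len(C)) {
        total <- total + counts[i, j]
        if (i == j) correct <- correct + counts[i, j]
    }
    for (c in seq_len(C)) {
        tp <- counts[c, c]
        fp <- 0; fn <- 0
        for (i in seq_len(C)) if (i != c) {
            fp <- fp + counts[i, c]
            fn <- fn + counts[c, i]
        }
        prec[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
        rec[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
        f1[c] <- if (prec[c] + rec[c] > 0)
            2 * prec[c] * rec[c] / (prec[c] + rec[c]) else 0
    }
    mp <- sum(prec) / C; mr <- sum(rec) / C
    list(accuracy = correct / total, precision = prec, recall = rec,
         f1 = f1, macroPrecision = mp, macroRecall = mr,
         macroF1 = sum(f1) / C,
         macroF1Paper = if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0)
}

## central finite differences over every element of `x`
numericGradient <- function(f, x, eps = 1e-5) {
    g <- x
    for (j in seq_along(x)) {
        xp <- x; xp[j] <- x[j] + eps
        xm <- x; xm[j] <- x[j] - eps
        g[j] <- (f(xp) - f(xm)) / (2 * eps)
    }
    g
}

## max relative disagreement, ignoring entries where both are ~0
maxRelErr <- function(a, b, floor = 1e-7) {
    denom <- pmax((abs(a) + abs(b)) / 2, floor)
    sel <- abs(a) > floor | abs(b) > floor
    if (!any(sel)) return(0)
    max(abs(a - b)[sel] / denom[sel])
}
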