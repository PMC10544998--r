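## Low-level numeric kernels for the miniature staged CNNs.
## Tensors are dense arrays with dimensions (channels, height, width, batch);
## convolutions are evaluated as 9 (or k^2) strided-slice matrix products,
## so the heavy lifting is BLAS GEMM. Backward passes are hand-derived
## adjoints of the same linear maps.

.zeros <- function(...) array(0, dim = c(...))

.padHW <- function(x, p) {
    if (p == 0) return(x)
    d <- dim(x)
    out <- .zeros(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4])
    out[, p + seq_len(d[2]), p + seq_len(d[3]), ] <- x
    out
}

convForward <- function(x, layer, keepCache = FALSE) {
    W <- layer$W; b <- layer$b
    s <- layer$stride; p <- layer$pad
    dW <- dim(W)                        # (Cout, Cin, kh, kw)
    dx <- dim(x)
    if (dx[1] != dW[2])
        stop("input has ", dx[1], " channels, conv expects ", dW[2])
    xp <- .padHW(x, p)
    dp <- dim(xp)
    hOut <- (dp[2] - dW[3]) %/% s + 1L
    wOut <- (dp[3] - dW[4]) %/% s + 1L
    ym <- matrix(0, dW[1], hOut * wOut * dx[4])
    xsList <- if (keepCache) vector("list", dW[3] * dW[4]) else NULL
    for (ki in seq_len(dW[3])) {
        hidx <- seq.int(ki, by = s, length.out = hOut)
        for (kj in seq_len(dW[4])) {
            widx <- seq.int(kj, by = s, length.out = wOut)
            xs <- xp[, hidx, widx, , drop = FALSE]
            dim(xs) <- c(dW[2], hOut * wOut * dx[4])
            wk <- matrix(W[, , ki, kj], dW[1], dW[2])
            ym <- ym + wk %*% xs
            if (keepCache) xsList[[(ki - 1) * dW[4] + kj]] <- xs
        }
    }
    ym <- ym + b
    y <- array(ym, dim = c(dW[1], hOut, wOut, dx[4]))
    if (keepCache)
        list(y = y, cache = list(xs = xsList, padDim = dp, hOut = hOut,
                                 wOut = wOut, inDim = dx))
    else list(y = y, cache = NULL)
}

convBackward <- function(layer, cache, dy) {
    W <- layer$W
    s <- layer$stride; p <- layer$pad
    dW4 <- dim(W)
    hOut <- cache$hOut; wOut <- cache$wOut
    n <- cache$inDim[4]
    dym <- matrix(dy, dW4[1], hOut * wOut * n)
    db <- rowSums(dym)
    gW <- array(0, dim = dW4)
    dxp <- array(0, dim = cache$padDim)
    for (ki in seq_len(dW4[3])) {
        hidx <- seq.int(ki, by = s, length.out = hOut)
        for (kj in seq_len(dW4[4])) {
            widx <- seq.int(kj, by = s, length.out = wOut)
            xs <- cache$xs[[(ki - 1) * dW4[4] + kj]]
            gW[, , ki, kj] <- tcrossprod(dym, xs)
            wk <- matrix(W[, , ki, kj], dW4[1], dW4[2])
            contrib <- crossprod(wk, dym)
            dim(contrib) <- c(dW4[2], hOut, wOut, n)
            dxp[, hidx, widx, ] <-
                dxp[, hidx, widx, , drop = FALSE] + contrib
        }
    }
    dx <- if (p > 0)
        dxp[, p + seq_len(cache$inDim[2]), p + seq_len(cache$inDim[3]), ,
            drop = FALSE]
    else dxp
    list(dx = dx, dW = gW, db = db)
}

reluForward <- function(x, keepCache = FALSE) {
    y <- x
    y[y < 0] <- 0
    list(y = y, cache = if (keepCache) list(mask = x > 0) else NULL)
}

reluBackward <- function(cache, dy) {
    dy * cache$mask
}

## global-average-pool + linear classification head
headForward <- function(x, layer, keepCache = FALSE) {
    d <- dim(x)
    hw <- d[2] * d[3]
    pooled <- rowMeans(array(aperm(x, c(1, 4, 2, 3)), c(d[1] * d[4], hw)))
    pooled <- matrix(pooled, d[1], d[4])
    logits <- layer$W %*% pooled + layer$b      # (nClasses, N)
    list(y = logits,
         cache = if (keepCache) list(pooled = pooled, inDim = d) else NULL)
}

headBackward <- function(layer, cache, dlogits) {
    d <- cache$inDim
    hw <- d[2] * d[3]
    dW <- dlogits %*% t(cache$pooled)
    db <- rowSums(dlogits)
    dpooled <- crossprod(layer$W, dlogits) / hw  # (C, N)
    ## broadcast dpooled over the spatial grid: build (C,N,H,W) then aperm
    dx <- aperm(array(dpooled, dim = c(d[1], d[4], d[2], d[3])),
                c(1, 3, 4, 2))
    list(dx = dx, dW = dW, db = db)
}

#' Bilinear resize of a feature-map batch (internal)
#'
#' Half-pixel-aligned separable bilinear interpolation on arrays shaped
#' (channels, height, width, batch). Exists because the feature-matching
#' loss needs an exact adjoint (transpose) of the interpolation for its
#' analytic gradient; image-file preprocessing uses EBImage::resize.
#'
#' @param x array (C, H, W, N).
#' @param outH,outW target spatial size.
#' @param adjointReady keep the interpolation matrices for
#'   [bilinearResizeAdjoint()].
#' @return list with `out` and (optionally) `Ry`, `Rx`.
#' @keywords internal
bilinearResize <- function(x, outH, outW, adjointReady = FALSE) {
    d <- dim(x)
    Ry <- .interpMatrix(d[2], outH)
    Rx <- .interpMatrix(d[3], outW)
    y <- .applyAlongDim(x, Ry, 2)
    y <- .applyAlongDim(y, Rx, 3)
    if (adjointReady) list(out = y, Ry = Ry, Rx = Rx) else list(out = y)
}

bilinearResizeAdjoint <- function(dy, rz) {
    g <- .applyAlongDim(dy, t(rz$Rx), 3)
    .applyAlongDim(g, t(rz$Ry), 2)
}

.interpCache <- new.env(parent = emptyenv())

.interpMatrix <- function(nIn, nOut) {
    key <- paste0(nIn, "_", nOut)
    hit <- .interpCache[[key]]
    if (!is.null(hit)) return(hit)
    R <- matrix(0, nOut, nIn)
    for (o in seq_len(nOut)) {
        src <- (o - 0.5) * nIn / nOut + 0.5
        i0 <- floor(src)
        w <- src - i0
        i0c <- min(max(i0, 1L), nIn)
        i1c <- min(max(i0 + 1, 1L), nIn)
        R[o, i0c] <- R[o, i0c] + (1 - w)
        R[o, i1c] <- R[o, i1c] + w
    }
    .interpCache[[key]] <- R
    R
}

.applyAlongDim <- function(x, R, along) {
    d <- dim(x)
    perm <- c(along, setdiff(1:4, along))
    xm <- matrix(aperm(x, perm), d[along])
    ym <- R %*% xm
    dnew <- c(nrow(R), d[-along])
    y <- array(ym, dim = dnew)
    aperm(y, order(perm))
}
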