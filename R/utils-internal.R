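# Internal plain-matrix machinery. The double-CV inner loop is the hot
# path; everything here works on bare matrices and integer label codes,
# and the S4 layer wraps it. Within an inner fold the PCA is fitted once
# at the largest candidate dimension and the scatter matrices of smaller
# candidates are read off as leading submatrices (score truncation),
# which is what keeps the repeated-split runs affordable.

# Evaluate expr with a local RNG state; the caller's stream is untouched.
.with_seed <- function(seed, expr) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(as.integer(seed))
    expr
}

# Lehmer-style mix keeping derived seeds inside 32-bit integer range and
# distinct from the seed+t replicate stream.
.derive_seed <- function(seed, k) {
    s <- (abs(as.double(seed)) * 48271 + as.double(k)) %% 2147483647
    as.integer(s) + 1L
}

.scale_fit <- function(X, mode) {
    n <- ncol(X)
    if (mode == "none")
        return(list(means = numeric(n), sds = rep(1, n), keep = rep(TRUE, n)))
    mu <- colMeans(X)
    if (mode == "center")
        return(list(means = mu, sds = rep(1, n), keep = rep(TRUE, n)))
    Xc <- sweep(X, 2L, mu, "-")
    sds <- sqrt(colSums(Xc * Xc) / (nrow(X) - 1L))
    keep <- sds > 0
    list(means = mu, sds = sds, keep = keep)
}

.scale_apply <- function(sc, X) {
    if (!all(sc$keep)) {
        X <- X[, sc$keep, drop = FALSE]
        means <- sc$means[sc$keep]; sds <- sc$sds[sc$keep]
    } else {
        means <- sc$means; sds <- sc$sds
    }
    X <- sweep(X, 2L, means, "-")
    if (!all(sds == 1)) X <- sweep(X, 2L, sds, "/")
    X
}

# Thin PCA of a pre-scaled matrix: center, SVD, keep a components.
# When features heavily outnumber samples the right singular vectors are
# recovered from the m x m Gram matrix (identical subspace, far cheaper
# than a direct SVD of the m x n matrix).
.pca_fit <- function(Xs, a) {
    ctr <- colMeans(Xs)
    Xc <- sweep(Xs, 2L, ctr, "-")
    m <- nrow(Xc); n <- ncol(Xc)
    if (n > 2L * m) {
        e <- eigen(tcrossprod(Xc), symmetric = TRUE)
        d2 <- pmax(e$values[seq_len(a)], 0)
        d <- sqrt(d2)
        V <- crossprod(Xc, e$vectors[, seq_len(a), drop = FALSE])
        V <- sweep(V, 2L, pmax(d, .Machine$double.eps), "/")
        list(center = ctr, loadings = V,
             scores = e$vectors[, seq_len(a), drop = FALSE] *
                 rep(d, each = m),
             singular = d)
    } else {
        sv <- svd(Xc, nu = 0L, nv = a)
        list(center = ctr, loadings = sv$v, scores = Xc %*% sv$v,
             singular = sv$d[seq_len(a)])
    }
}

# Scatter matrices of integer-coded labels y in 1..r on score matrix S.
.scatter <- function(S, y, r) {
    counts <- tabulate(y, nbins = r)
    cent <- rowsum(S, y, reorder = TRUE) / counts       # r x a
    grand <- colSums(S) / nrow(S)
    D <- sweep(cent, 2L, grand, "-")
    Sb <- crossprod(D * sqrt(counts))
    Sw <- crossprod(S - cent[y, , drop = FALSE])
    list(Sb = Sb, Sw = Sw, centroids = cent, grand = grand, counts = counts)
}

# Top-q generalized eigenvectors of (Sb, Sw) via Cholesky of Sw;
# columns unit norm, largest-magnitude entry positive, eigenvalues
# (Rayleigh quotients) decreasing.
.fisher <- function(Sb, Sw, q) {
    U <- tryCatch(chol(Sw), error = function(e)
        stop("within-class scatter is singular in the projected space; ",
             "lower the number of principal components", call. = FALSE))
    if (q == 1L && max(diag(Sb)) > 0) {
        # rank-1 between-class scatter (two classes): the top generalized
        # eigenvector is Sw^{-1} b for any nonzero column b of Sb = c bb'
        j <- which.max(diag(Sb))
        d <- backsolve(U, forwardsolve(t(U), Sb[, j]))
        d <- d / sqrt(sum(d * d))
        i <- which.max(abs(d))
        if (d[i] < 0) d <- -d
        lam <- drop(crossprod(d, Sb %*% d) / crossprod(d, Sw %*% d))
        return(list(directions = matrix(d, ncol = 1L), eigenvalues = lam))
    }
    L <- t(U)
    tmp <- forwardsolve(L, Sb)
    B <- forwardsolve(L, t(tmp))
    B <- (B + t(B)) / 2
    e <- eigen(B, symmetric = TRUE)
    V <- e$vectors[, seq_len(q), drop = FALSE]
    D <- backsolve(U, V)
    for (j in seq_len(q)) {
        d <- D[, j]
        d <- d / sqrt(sum(d * d))
        i <- which.max(abs(d))
        if (d[i] < 0) d <- -d
        D[, j] <- d
    }
    list(directions = D, eigenvalues = e$values[seq_len(q)])
}

# Nearest projected centroid, ties to the lowest class index.
.nearest_centroid <- function(P, Cp) {
    d2 <- outer(rowSums(P * P), rowSums(Cp * Cp), "+") - 2 * P %*% t(Cp)
    max.col(-d2, ties.method = "first")
}

# Full PCDA fit on plain matrices; y integer codes 1..r.
.pcda_fit <- function(X, y, r, a, mode) {
    m <- nrow(X)
    if (a > m - r)
        stop("nComponents must be <= training samples - classes (",
             m - r, ") so the within-class scatter stays invertible")
    sc <- .scale_fit(X, mode)
    Xs <- .scale_apply(sc, X)
    if (a > min(m - 1L, ncol(Xs)))
        stop("nComponents out of range: must be <= min(m - 1, n)")
    p <- .pca_fit(Xs, a)
    st <- .scatter(p$scores, y, r)
    q <- min(r - 1L, a)
    f <- .fisher(st$Sb, st$Sw, q)
    list(scaler = sc, center = p$center, loadings = p$loadings,
         directions = f$directions, eigenvalues = f$eigenvalues,
         centroids_proj = st$centroids %*% f$directions, a = a, r = r)
}

.pcda_predict <- function(fit, X) {
    Xs <- .scale_apply(fit$scaler, X)
    S <- sweep(Xs, 2L, fit$center, "-") %*% fit$loadings
    .nearest_centroid(S %*% fit$directions, fit$centroids_proj)
}

# Inner-loop component selection: stratified Kin-fold CV over the
# candidate grid, one SVD per fold at the largest candidate.
.select_ncomp <- function(X, y, r, Kin, candidates, mode, seed) {
    folds <- .strat_folds(y, r, Kin, seed)
    min_train <- nrow(X) - max(tabulate(folds, nbins = Kin))
    cands <- candidates[candidates <= min(min_train - r, min_train - 1L, ncol(X))]
    if (!length(cands))
        stop("no feasible candidate component count for inner folds of ",
             min_train, " training samples and ", r, " classes")
    errs <- numeric(length(cands))
    amax <- max(cands)
    for (j in seq_len(Kin)) {
        te <- folds == j
        Xtr <- X[!te, , drop = FALSE]; ytr <- y[!te]
        sc <- .scale_fit(Xtr, mode)
        Str_full <- .pca_fit(.scale_apply(sc, Xtr), amax)
        Sva <- sweep(.scale_apply(sc, X[te, , drop = FALSE]),
                     2L, Str_full$center, "-") %*% Str_full$loadings
        st <- .scatter(Str_full$scores, ytr, r)
        yva <- y[te]
        for (ci in seq_along(cands)) {
            a <- cands[ci]
            idx <- seq_len(a)
            q <- min(r - 1L, a)
            f <- .fisher(st$Sb[idx, idx, drop = FALSE],
                         st$Sw[idx, idx, drop = FALSE], q)
            cp <- st$centroids[, idx, drop = FALSE] %*% f$directions
            pred <- .nearest_centroid(Sva[, idx, drop = FALSE] %*% f$directions, cp)
            errs[ci] <- errs[ci] + sum(pred != yva)
        }
    }
    list(best = cands[which.min(errs)], candidates = cands,
         errors = errs / nrow(X))
}

# Round-robin stratified K-fold assignment (1..K) after a seeded
# within-class shuffle; per class, fold counts differ by at most one.
.strat_folds <- function(y, r, K, seed) {
    counts <- tabulate(y, nbins = r)
    if (K > min(counts))
        stop("K = ", K, " exceeds the smallest class size (", min(counts),
             "); every fold must contain every class")
    folds <- integer(length(y))
    .with_seed(seed, {
        for (cl in seq_len(r)) {
            idx <- which(y == cl)
            idx <- idx[sample.int(length(idx))]
            folds[idx] <- rep_len(seq_len(K), length(idx))
        }
    })
    folds
}

# One full double-CV pass on plain matrices.
.double_cv <- function(X, y, r, K, candidates, mode, seed) {
    folds <- .strat_folds(y, r, K, seed)
    m <- nrow(X)
    pred <- integer(m)
    sel <- integer(K)
    fits <- vector("list", K)
    for (i in seq_len(K)) {
        te <- folds == i
        Xi <- X[!te, , drop = FALSE]; yi <- y[!te]
        cands <- candidates
        if (!length(cands)) {
            inner_min_train <- length(yi) -
                max(tabulate(.strat_folds(yi, r, K - 1L, .derive_seed(seed, i)),
                             nbins = K - 1L))
            cands <- seq_len(max(1L, min(20L, inner_min_train - r)))
        }
        selres <- .select_ncomp(Xi, yi, r, K - 1L, cands, mode,
                                .derive_seed(seed, i))
        sel[i] <- selres$best
        fit <- .pcda_fit(Xi, yi, r, selres$best, mode)
        fits[[i]] <- fit
        pred[te] <- .pcda_predict(fit, X[te, , drop = FALSE])
    }
    list(folds = folds, selected = sel, predictions = pred,
         fits = fits, error = mean(pred != y))
}

# Wrap a plain fit into a PCDAModel (feature bookkeeping post scaler drop).
.as_model <- function(fit, featureNames, classLabels) {
    kept <- featureNames[fit$scaler$keep]
    new("PCDAModel",
        scaler = new("ScalerParams",
            featureMeans = fit$scaler$means[fit$scaler$keep],
            featureSds = fit$scaler$sds[fit$scaler$keep],
            mode = if (all(fit$scaler$sds == 1) && all(fit$scaler$means == 0))
                       "none"
                   else if (all(fit$scaler$sds == 1)) "center" else "autoscale",
            featureNames = kept,
            droppedFeatures = featureNames[!fit$scaler$keep]),
        pcaMean = fit$center,
        pcaLoadings = fit$loadings,
        nComponents = fit$a,
        directions = fit$directions,
        centroids = fit$centroids_proj,
        classLabels = classLabels,
        featureNames = featureNames)
}

# Recover the plain-fit form of a PCDAModel for the fast predictors.
.as_fit <- function(model) {
    nAll <- length(model@featureNames)
    keep <- model@featureNames %in% model@scaler@featureNames
    means <- numeric(nAll); sds <- rep(1, nAll)
    means[keep] <- model@scaler@featureMeans
    sds[keep] <- model@scaler@featureSds
    list(scaler = list(means = means, sds = sds, keep = keep),
         center = model@pcaMean, loadings = model@pcaLoadings,
         directions = model@directions, centroids_proj = model@centroids,
         a = model@nComponents, r = length(model@classLabels))
}

.check_features <- function(model, x) {
    fn <- if (is(x, "LabeledMatrix")) x@featureNames else colnames(x)
    if (!is.null(fn) && !identical(fn, model@featureNames) &&
        length(fn) == length(model@featureNames))
        return(invisible(TRUE))  # same count, unnamed or renamed: accept
    if (is.null(fn)) {
        if (ncol(if (is(x, "LabeledMatrix")) x@values else x) !=
            length(model@featureNames))
            stop("feature count mismatch: model expects ",
                 length(model@featureNames), " features")
        return(invisible(TRUE))
    }
    if (length(fn) != length(model@featureNames))
        stop("feature count mismatch: model expects ",
             length(model@featureNames), " features, got ", length(fn))
    invisible(TRUE)
}
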