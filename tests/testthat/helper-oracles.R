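# independent brute-force oracles, kept free of package internals

# binomial deviance dissimilarity summed taxon by taxon
bruteBinomial <- function(m) {
    n <- ncol(m)
    d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
    xlx <- function(x) ifelse(x > 0, x * log(x), 0)
    for (j in seq_len(n - 1)) for (k in (j + 1):n) {
        x <- m[, j]; y <- m[, k]; tot <- x + y
        use <- tot > 0
        term <- (xlx(x[use]) - x[use] * log(tot[use]) +
                 xlx(y[use]) - y[use] * log(tot[use]) +
                 tot[use] * log(2)) / tot[use]
        d[j, k] <- d[k, j] <- sum(term)
    }
    stats::as.dist(d)
}

# zero-tolerant median-of-ratios size factors, step by step
brutePoscounts <- function(m) {
    nsamp <- ncol(m)
    r <- apply(m, 1, function(row) prod(row[row > 0])^(1 / nsamp))
    sf <- sapply(seq_len(nsamp), function(j) {
        use <- r > 0 & m[, j] > 0
        stats::median(m[use, j] / r[use])
    })
    sf / exp(mean(log(sf)))
}

# step-up FDR by its definition: padj_(i) = min_{k >= i} m p_(k) / k
bruteBH <- function(p) {
    ord <- order(p)
    mlen <- length(p)
    out <- numeric(mlen)
    for (k in seq_len(mlen))
        out[ord[k]] <- min(1, min(mlen * p[ord][k:mlen] /
                                  seq_len(mlen)[k:mlen]))
    out
}
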