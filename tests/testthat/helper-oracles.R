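# Independent oracles and small fixture builders used across the suite.

# Naive full-matrix Smith-Waterman with affine gaps (a gap of length L costs
# open + L * ext), written independently of the package's aligner. Returns
# the optimal local score.
sw_oracle_score <- function(a, b, mat, open = 11, ext = 1) {
    A <- strsplit(a, "")[[1]]
    B <- strsplit(b, "")[[1]]
    n <- length(A)
    m <- length(B)
    NEG <- -1e9
    M_prev <- rep(0, m + 1L)
    Ix_prev <- Iy_prev <- rep(NEG, m + 1L)
    best <- 0
    for (i in seq_len(n)) {
        Ix_row <- pmax(M_prev - open - ext, Ix_prev - ext)
        svec <- mat[A[i], B]
        diag_best <- pmax(M_prev[1:m], Ix_prev[1:m], Iy_prev[1:m])
        M_row <- c(0, pmax(0, svec + diag_best))
        Iy_row <- rep(NEG, m + 1L)
        for (j in 2:(m + 1L))
            Iy_row[j] <- max(M_row[j - 1L] - open - ext, Iy_row[j - 1L] - ext)
        best <- max(best, M_row)
        M_prev <- M_row
        Ix_prev <- Ix_row
        Iy_prev <- Iy_row
    }
    best
}

# Exhaustive least-squares oracle for 4-taxon trees: fits all three
# unrooted topologies by linear least squares and returns the best.
# Topology is reported as the pair grouped with the first taxon.
nj_ls_oracle <- function(d) {
    taxa <- rownames(d)
    stopifnot(length(taxa) == 4L)
    splits <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L))
    fit_one <- function(pair) {
        other <- setdiff(1:4, pair)
        # unknowns: t1..t4 (terminal), e (internal)
        rows <- utils::combn(4L, 2L)
        X <- matrix(0, ncol(rows), 5L)
        y <- numeric(ncol(rows))
        same_side <- function(i, j)
            (i %in% pair) == (j %in% pair)
        for (k in seq_len(ncol(rows))) {
            i <- rows[1L, k]; j <- rows[2L, k]
            X[k, i] <- 1; X[k, j] <- 1
            if (!same_side(i, j)) X[k, 5L] <- 1
            y[k] <- d[i, j]
        }
        beta <- qr.solve(X, y)
        rss <- sum((X %*% beta - y)^2)
        list(pair = pair, lengths = beta[1:4], internal = beta[5L], rss = rss)
    }
    fits <- lapply(splits, fit_one)
    best <- fits[[which.min(vapply(fits, `[[`, 0, "rss"))]]
    best$sister_of_1 <- taxa[setdiff(best$pair, 1L)]
    names(best$lengths) <- taxa
    best
}

# Branch length of the edge leading to a tip of a phylo tree.
tip_branch_length <- function(tree, tip) {
    tree$edge.length[match(match(tip, tree$tip.label), tree$edge[, 2L])]
}

# Additive distance matrix from an unrooted 4-taxon tree given as terminal
# lengths (named by taxon), the internal length and the split with taxon 1.
additive_4taxon <- function(lengths, internal, pair) {
    taxa <- names(lengths)
    d <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
    for (i in 1:3) for (j in (i + 1):4) {
        extra <- if ((i %in% pair) == (j %in% pair)) 0 else internal
        d[i, j] <- d[j, i] <- lengths[i] + lengths[j] + extra
    }
    d
}

# Wrap a plain matrix as a PresenceAbsenceMatrix.
pam <- function(m, fams = NULL, strains = NULL) {
    if (is.null(rownames(m)))
        rownames(m) <- if (is.null(fams)) sprintf("f%03d", seq_len(nrow(m)))
                       else fams
    if (is.null(colnames(m)))
        colnames(m) <- if (is.null(strains)) sprintf("s%02d", seq_len(ncol(m)))
                       else strains
    storage.mode(m) <- "integer"
    new("PresenceAbsenceMatrix", counts = m)
}

# Random proteome-free presence-absence matrix for fuzzing.
random_pam <- function(nfam, nstrain) {
    repeat {
        m <- matrix(rbinom(nfam * nstrain, 2L, 0.4), nfam, nstrain)
        if (all(rowSums(m) > 0)) break
    }
    pam(m)
}

# Random protein of given length over the 20-letter alphabet.
random_protein <- function(len) {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
                 replace = TRUE), collapse = "")
}

# Mutate a fraction of positions of a protein to different residues.
mutate_protein <- function(seq, frac) {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    x <- strsplit(seq, "")[[1]]
    idx <- sample(length(x), round(frac * length(x)))
    for (i in idx) x[i] <- sample(setdiff(aa, x[i]), 1L)
    paste(x, collapse = "")
}

# The package's BLOSUM62 variant (X scored 0), for the oracle.
blosum62_x0 <- function() {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    m["X", ] <- 0L
    m[, "X"] <- 0L
    m
}

# True family label of a simulated gene id ("<strain>.<family>").
true_family_of <- function(gene_ids) sub("^S[0-9]+\\.", "", gene_ids)

# Recovered-vs-true clustering agreement on a simulation.
cluster_recovery <- function(sim) {
    genes <- geneTable(sim)[c("gene_id", "strain")]
    hits <- allVsAll(proteomes(sim))
    fams <- clusterFamilies(hits, genes)
    list(true = true_family_of(genes$gene_id),
         recovered = fams$family_id[match(genes$gene_id, fams$gene_id)],
         families = fams)
}
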