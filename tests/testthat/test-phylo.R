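test_that("single-copy core selection requires exactly one copy everywhere", {
    m <- pam(rbind(c(1, 1), c(2, 1), c(1, 0)),
             fams = c("f1", "f2", "f3"), strains = c("s1", "s2"))
    expect_identical(singleCopyCore(m), "f1")
    sim <- simulateStrains(simulationConfig(nStrains = 4, nCore = 12,
                                            dispensableRate = 0,
                                            uniquePerStrain = 0, seed = 2))
    rec <- cluster_recovery(sim)
    expect_length(singleCopyCore(buildMatrix(rec$families)), 12L)
})

test_that("concatenated p-distances count differing pooled columns", {
    # 3 strains, one family of 500 aa; s2 differs from s1 at exactly 5 sites
    set.seed(6)
    base <- random_protein(500)
    variant <- base
    idx <- sample(500, 5)
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    v <- strsplit(variant, "")[[1]]
    for (i in idx) v[i] <- sample(setdiff(aa, v[i]), 1)
    variant <- paste(v, collapse = "")
    prot <- list(s1 = Biostrings::AAStringSet(c(g1 = base)),
                 s2 = Biostrings::AAStringSet(c(g2 = variant)),
                 s3 = Biostrings::AAStringSet(c(g3 = base)))
    fams <- data.frame(family_id = "f1", strain = c("s1", "s2", "s3"),
                       gene_id = c("g1", "g2", "g3"))
    d <- concatDistances(fams, prot)
    expect_equal(d["s1", "s2"], 0.01)
    expect_equal(d["s1", "s3"], 0)
    expect_equal(unname(diag(d)), c(0, 0, 0))
    expect_equal(d, t(d))
    # claiming a family that is missing a member is a consistency error
    bad <- fams[1:2, ]
    expect_error(concatDistances(bad, prot, familyIds = "f1"),
                 "single-copy")
})

test_that("NJ recovers the 4-taxon additive example exactly", {
    lengths <- c(A = 1, B = 2, C = 3, D = 4)
    d <- additive_4taxon(lengths, internal = 1, pair = c(1L, 2L))
    tr <- njTree(d)
    # oracle: exhaustive least squares over the 3 topologies
    oracle <- nj_ls_oracle(d)
    expect_identical(oracle$sister_of_1, "B")
    expect_equal(unname(oracle$lengths), unname(lengths))
    expect_equal(oracle$internal, 1)
    # the NJ tree shows the same split and branch lengths
    expect_equal(as.numeric(ape::dist.topo(tr, ape::read.tree(
        text = "((A:1,B:2):1,C:3,D:4);"))), 0)
    for (tip in names(lengths))
        expect_equal(tip_branch_length(tr, tip), unname(lengths[tip]))
    internal_edge <- setdiff(seq_along(tr$edge.length),
                             match(seq_along(tr$tip.label), tr$edge[, 2]))
    expect_equal(unname(tr$edge.length[internal_edge]), 1)
})

test_that("3-taxon trees use the closed-form branch lengths", {
    d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
    tr <- njTree(d)
    expect_equal(tip_branch_length(tr, "a"), 1)
    expect_equal(tip_branch_length(tr, "b"), 2)
    expect_equal(tip_branch_length(tr, "c"), 3)
})

test_that("NJ reconstructs random additive trees and matches ape", {
    set.seed(19)
    for (k in 1:12) {
        n <- sample(5:8, 1)
        tr0 <- ape::rtree(n, br = function(x) runif(x, 0.5, 3))
        d <- ape::cophenetic.phylo(tr0)
        d <- d[sort(rownames(d)), sort(colnames(d))]
        tr <- njTree(d)
        expect_equal(as.numeric(ape::dist.topo(tr, ape::unroot(tr0))), 0)
        expect_equal(as.numeric(ape::dist.topo(tr, ape::nj(as.dist(d)))), 0)
        # recovered tree reproduces the additive distances
        expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
                     tolerance = 1e-8)
    }
})

test_that("NJ input validation and negative-branch clamping", {
    d <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
    expect_error(njTree(d), "symmetric")
    # near-zero distances never produce negative branch lengths
    d2 <- matrix(0.001, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    diag(d2) <- 0
    expect_true(all(njTree(d2)$edge.length >= 0))
})

test_that("synthetic panels recover the true tree topology", {
    ok <- 0L
    seeds <- c(4, 15, 27)
    for (seed in seeds) {
        sim <- simulateStrains(simulationConfig(
            nStrains = 6, nCore = 15, dispensableRate = 0,
            uniquePerStrain = 0, perBranchDivergence = 0.02, seed = seed))
        rec <- cluster_recovery(sim)
        d <- concatDistances(rec$families, proteomes(sim))
        tr <- njTree(d)
        truth <- ape::unroot(groundTruth(sim)@tree)
        if (ape::dist.topo(tr, truth) == 0) ok <- ok + 1L
        # distances correlate with true path lengths
        paths <- ape::cophenetic.phylo(groundTruth(sim)@tree)
        paths <- paths[rownames(d), colnames(d)]
        expect_gt(cor(d[upper.tri(d)], paths[upper.tri(paths)]), 0.9)
    }
    expect_gte(ok, 2L)
})

test_that("family bootstrap is reproducible and saturates on clean signal", {
    sim <- simulateStrains(simulationConfig(
        nStrains = 5, nCore = 10, dispensableRate = 0, uniquePerStrain = 0,
        perBranchDivergence = 0.03, seed = 9))
    rec <- cluster_recovery(sim)
    b1 <- bootstrapSupport(rec$families, proteomes(sim), nReps = 50,
                           seed = 42)
    b2 <- bootstrapSupport(rec$families, proteomes(sim), nReps = 50,
                           seed = 42)
    expect_identical(ape::write.tree(b1), ape::write.tree(b2))
    expect_identical(b1$node.label, b2$node.label)
    sup <- b1$node.label[!is.na(b1$node.label)]
    expect_true(all(sup >= 0 & sup <= 100))
    # identical signal in every family: each family reuses the same
    # per-strain variant, so resampling families cannot change the tree
    base <- random_protein(100)
    prot <- list()
    for (s in c("s1", "s2", "s3", "s4")) {
        v <- mutate_protein(base, 0.1)
        prot[[s]] <- Biostrings::AAStringSet(
            setNames(rep(v, 3), paste0(s, ".g", 1:3)))
    }
    fams <- do.call(rbind, lapply(1:3, function(f)
        data.frame(family_id = paste0("f", f), strain = names(prot),
                   gene_id = paste0(names(prot), ".g", f))))
    bs <- bootstrapSupport(fams, prot, nReps = 30, seed = 1)
    expect_true(all(is.na(bs$node.label) | bs$node.label == 100))
})

test_that("distance matrices round-trip through PHYLIP square format", {
    d <- matrix(c(0, 0.1, 0.2, 0.1, 0, 0.15, 0.2, 0.15, 0), 3, 3,
                dimnames = list(c("t1", "t2", "t3"), c("t1", "t2", "t3")))
    path <- tempfile(fileext = ".phy")
    writePhylip(d, path)
    back <- readPhylip(path)
    expect_equal(back, d, tolerance = 1e-8)
    unlink(path)
})
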