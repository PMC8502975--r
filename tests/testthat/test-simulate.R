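test_that("zero-divergence, zero-accessory panel gives identical strains", {
    cfg <- simulationConfig(nStrains = 2, nCore = 5, dispensableRate = 0,
                            uniquePerStrain = 0, perBranchDivergence = 0,
                            spacerIndelRate = 0, seed = 3)
    sim <- simulateStrains(cfg)
    tab <- groundTruth(sim)@familyTable
    expect_identical(dim(tab), c(5L, 2L))
    expect_true(all(tab == 1L))
    p <- proteomes(sim)
    expect_identical(unname(as.character(p$S01)), unname(as.character(p$S02)))
    expect_identical(as.character(genomes(sim)[["S01"]]),
                     as.character(genomes(sim)[["S02"]]))
    expect_true(all(groundTruth(sim)@trueAni == 1))
})

test_that("identical config and seed reproduce the panel byte-for-byte", {
    cfg <- simulationConfig(nStrains = 4, nCore = 8, seed = 17)
    s1 <- simulateStrains(cfg)
    s2 <- simulateStrains(cfg)
    expect_identical(as.character(genomes(s1)), as.character(genomes(s2)))
    expect_identical(geneTable(s1), geneTable(s2))
    expect_identical(groundTruth(s1)@familyTable, groundTruth(s2)@familyTable)
    d1 <- file.path(tempdir(), "simA")
    d2 <- file.path(tempdir(), "simB")
    writeStrainData(s1, d1)
    writeStrainData(s2, d2)
    for (f in list.files(d1)) {
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         info = f)
    }
    unlink(c(d1, d2), recursive = TRUE)
})

test_that("gene counts are conserved against the ground-truth table", {
    for (seed in c(1, 9)) {
        sim <- simulateStrains(simulationConfig(nStrains = 5, seed = seed))
        tab <- groundTruth(sim)@familyTable
        counts <- vapply(proteomes(sim), length, 0L)
        expect_identical(unname(counts[colnames(tab)]),
                         unname(as.integer(colSums(tab))))
    }
    # with a planted cluster the extra genes are tracked separately
    sim <- simulateStrains(simulationConfig(
        nStrains = 3, seed = 2,
        hgtCluster = list(n_genes = 2, gc_shift = 0.08,
                          donor_label = "donor")))
    truth <- groundTruth(sim)
    tab <- truth@familyTable
    counts <- vapply(proteomes(sim), length, 0L)[colnames(tab)]
    extra <- table(factor(truth@hgtCoords$strain, colnames(tab)))
    expect_identical(unname(counts),
                     unname(as.integer(colSums(tab)) + as.integer(extra)))
    expect_length(truth@hgtGeneIds, 2L)
    expect_false(any(truth@hgtGeneIds %in%
                     paste0(rep(colnames(tab), each = nrow(tab)), ".",
                            rownames(tab))))
})

test_that("strain-specific family counts follow the configured Poisson mean", {
    lambda <- 2
    tot <- 0L
    n_tips <- 0L
    for (seed in 1:200) {
        truth <- simulateFamilyTable(simulationConfig(
            nStrains = 3, nCore = 2, dispensableRate = 0,
            uniquePerStrain = lambda, seed = seed))
        tab <- truth@familyTable
        tot <- tot + sum(startsWith(rownames(tab), "F.u."))
        n_tips <- n_tips + ncol(tab)
    }
    mean_per_tip <- tot / n_tips
    se <- sqrt(lambda / n_tips)
    expect_lt(abs(mean_per_tip - lambda), 4 * se)
})

test_that("two-branch divergence yields the closed-form ortholog identity", {
    p <- 0.015
    cfg <- simulationConfig(nStrains = 2, nCore = 40, dispensableRate = 0,
                            uniquePerStrain = 0, perBranchDivergence = p,
                            spacerIndelRate = 0, seed = 5)
    sim <- simulateStrains(cfg)
    g1 <- geneTable(sim)[geneTable(sim)$strain == "S01", ]
    ids1 <- g1$gene_id
    ids2 <- sub("^S01", "S02", ids1)
    s1 <- paste(as.character(proteomes(sim)$S01[ids1]), collapse = "")
    # compare at the nucleotide level via the genomes' gene coordinates
    nt_same <- 0L
    nt_tot <- 0L
    gt <- geneTable(sim)
    for (k in seq_along(ids1)) {
        r1 <- gt[gt$gene_id == ids1[k], ]
        r2 <- gt[gt$gene_id == ids2[k], ]
        a <- strsplit(as.character(Biostrings::subseq(
            genomes(sim)[["S01"]], r1$start + 1L, r1$end)), "")[[1]]
        b <- strsplit(as.character(Biostrings::subseq(
            genomes(sim)[["S02"]], r2$start + 1L, r2$end)), "")[[1]]
        nt_same <- nt_same + sum(a == b)
        nt_tot <- nt_tot + length(a)
    }
    expected <- (1 - p)^2
    se <- sqrt(expected * (1 - expected) / nt_tot)
    expect_lt(abs(nt_same / nt_tot - expected), 5 * se + 1e-4)
    expect_equal(groundTruth(sim)@trueAni["S01", "S02"], expected)
})

test_that("raising the unique-gene rate increases expected pan-genome size", {
    pan_size <- function(u) {
        vapply(1:100, function(seed) {
            nrow(simulateFamilyTable(simulationConfig(
                nStrains = 4, nCore = 5, dispensableRate = 0,
                uniquePerStrain = u, seed = seed))@familyTable)
        }, 0)
    }
    expect_gt(mean(pan_size(3)), mean(pan_size(0.5)))
})

test_that("planted cluster has shifted GC and recorded coordinates", {
    sim <- simulateStrains(simulationConfig(
        nStrains = 2, nCore = 30, dispensableRate = 0, uniquePerStrain = 0,
        backgroundGC = 0.42, seed = 8,
        hgtCluster = list(n_genes = 4, gc_shift = 0.1,
                          donor_label = "Brevibacillus")))
    truth <- groundTruth(sim)
    co <- truth@hgtCoords
    expect_identical(nrow(co), 4L)
    expect_identical(length(unique(co$strain)), 1L)
    g <- genomes(sim)[[co$strain[1]]]
    cluster_gc <- gcContent(Biostrings::subseq(g, min(co$start) + 1L,
                                               max(co$end)))
    expect_gt(cluster_gc, 0.47)
    expect_lt(gcContent(g), cluster_gc)
    expect_identical(truth@donorLabel, "Brevibacillus")
    expect_length(truth@donorSeqs, 4L)
    # planted genes are real CDS rows of the recipient
    gt <- geneTable(sim)
    expect_true(all(truth@hgtGeneIds %in% gt$gene_id))
})

test_that("invalid configurations are rejected naming the offending field", {
    expect_error(simulationConfig(nStrains = 1), "n_strains")
    expect_error(simulationConfig(nCore = 0), "n_core")
    expect_error(simulationConfig(dispensableRate = -1), "dispensable_rate")
    expect_error(simulationConfig(backgroundGC = 1), "background_gc")
    expect_error(simulationConfig(perBranchDivergence = 1.5),
                 "per_branch_divergence")
    expect_error(simulationConfig(
        hgtCluster = list(n_genes = 2, gc_shift = 0.9,
                          donor_label = "d")), "gc_shift")
})

test_that("evolveSequence hits the expected identity and clade panels are blocky", {
    set.seed(42)
    x <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
    y <- evolveSequence(x, 0.1)
    ident <- mean(strsplit(x, "")[[1]] == strsplit(y, "")[[1]])
    expect_lt(abs(ident - 0.9), 0.02)
    expect_error(evolveSequence(x, 1.2), "rate")

    panel <- simulateCladePanel(nClades = 2, strainsPerClade = 2,
                                withinRate = 0.01, betweenRate = 0.2,
                                genomeLen = 2000, seed = 6)
    expect_length(panel$genomes, 4L)
    w <- function(a, b) mean(strsplit(as.character(panel$genomes[[a]]),
                                      "")[[1]] ==
                             strsplit(as.character(panel$genomes[[b]]),
                                      "")[[1]])
    expect_gt(w("C1S1", "C1S2"), 0.95)
    expect_lt(w("C1S1", "C2S1"), 0.8)
})
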