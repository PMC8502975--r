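test_that("gcContent follows the counting rules", {
    expect_equal(gcContent("ATGC"), 0.5)
    expect_equal(gcContent("GGCC"), 1)
    expect_equal(gcContent("ATNNAT"), 0)   # N excluded from both sides
    expect_error(gcContent(""), "genomeA|single|empty")
    expect_error(gcContent("NNNN"), "unambiguous")
    set.seed(3)
    for (k in 1:5) {
        s <- paste(sample(c("A", "C", "G", "T", "N"), 300, TRUE),
                   collapse = "")
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s)))
        expect_equal(gcContent(s), gcContent(rc))
    }
})

test_that("gcZscore is near zero on homogeneous genomes and validates bounds", {
    set.seed(8)
    g <- paste(sample(c("A", "C", "G", "T"), 8000, TRUE), collapse = "")
    res <- gcZscore(g, 3000, 3800)
    expect_lt(abs(res$z_score), 2)
    expect_false(res$gc_flagged)
    expect_equal(res$window_len, 800)
    # determinism: identical call, identical result
    expect_identical(res, gcZscore(g, 3000, 3800))
    expect_error(gcZscore(g, -1, 100), "invalid cluster")
    expect_error(gcZscore(g, 100, 50), "invalid cluster")
    expect_error(gcZscore(paste(rep("A", 100), collapse = ""), 0, 500),
                 "longer than genome")
})

test_that("window z-scores of the genome against itself average to zero", {
    set.seed(12)
    g <- paste(sample(c("A", "C", "G", "T"), 6000, TRUE,
                      prob = c(0.29, 0.21, 0.21, 0.29)), collapse = "")
    wl <- 500L
    step <- 50L
    zs <- vapply(seq(0L, 6000L - wl, by = step), function(s) {
        r <- gcZscore(g, s, s + wl, step = step)
        (r$cluster_gc - r$background_mean) / r$background_sd
    }, 0)
    expect_lt(abs(mean(zs)), 0.2)
})

test_that("a strongly GC-shifted planted cluster is flagged", {
    sim <- simulateStrains(simulationConfig(
        nStrains = 2, nCore = 40, dispensableRate = 0, uniquePerStrain = 0,
        backgroundGC = 0.42, seed = 51,
        hgtCluster = list(n_genes = 6, gc_shift = 0.08,
                          donor_label = "Brevibacillus")))
    co <- groundTruth(sim)@hgtCoords
    res <- gcZscore(genomes(sim)[[co$strain[1]]], min(co$start), max(co$end))
    expect_true(res$gc_flagged)
    expect_gt(res$z_score, 2)
    expect_gt(res$cluster_gc, res$genome_gc)
})

test_that("detection power increases with the GC shift", {
    rate_for <- function(shift, seeds) {
        mean(vapply(seeds, function(i) {
            sim <- simulateStrains(simulationConfig(
                nStrains = 2, nCore = 40, dispensableRate = 0,
                uniquePerStrain = 0, backgroundGC = 0.42, seed = i,
                hgtCluster = list(n_genes = 6, gc_shift = shift,
                                  donor_label = "d")))
            co <- groundTruth(sim)@hgtCoords
            abs(gcZscore(genomes(sim)[[co$strain[1]]], min(co$start),
                         max(co$end))$z_score)
        }, 0))
    }
    seeds <- 1:8
    z2 <- rate_for(0.02, seeds)
    z5 <- rate_for(0.05, seeds)
    z8 <- rate_for(0.08, seeds)
    expect_lt(z2, z5)
    expect_lt(z5, z8)
})

test_that("placement stays home for a self-genus gene and ties break low", {
    set.seed(14)
    a <- random_protein(90)
    b <- mutate_protein(a, 0.3)
    far1 <- random_protein(90)
    far2 <- mutate_protein(far1, 0.1)
    panel <- Biostrings::AAStringSet(c(self1 = a, self2 = b,
                                       out1 = far1, out2 = far2))
    genera <- c("Bacillus", "Bacillus", "Paenibacillus", "Paenibacillus")
    res <- placementTest(a, panel, genera, "Bacillus")
    expect_false(res$placement_flagged)
    expect_identical(res$placement_taxon, "Bacillus")
    # symmetric construction: query identical to one member of each genus
    panel2 <- Biostrings::AAStringSet(c(p1 = a, p2 = a,
                                        o1 = far1, o2 = far2))
    genera2 <- c("Beta", "Alpha", "Gamma", "Gamma")
    res2 <- placementTest(a, panel2, genera2, "Beta")
    expect_true(res2$tie)
    expect_identical(res2$placement_taxon, "Alpha")   # lexicographic
    expect_error(placementTest(a, panel[1:2], genera[1:2], "Bacillus"),
                 "3 sequences")
    expect_error(placementTest(a, panel, rep("Bacillus", 4), "Bacillus"),
                 "2 genus")
})

test_that("a donor-derived planted gene places into the donor lineage", {
    sim <- simulateStrains(simulationConfig(
        nStrains = 2, nCore = 10, dispensableRate = 0, uniquePerStrain = 0,
        perBranchDivergence = 0.02, seed = 33,
        hgtCluster = list(n_genes = 2, gc_shift = 0.08,
                          donor_label = "Brevibacillus")))
    truth <- groundTruth(sim)
    s <- truth@hgtCoords$strain[1]
    prot <- proteomes(sim)[[s]]
    donors <- Biostrings::translate(
        truth@donorSeqs, genetic.code = Biostrings::getGeneticCode("11"))
    self <- prot[grep("\\.F\\.c", names(prot))[1:3]]
    panel <- c(donors, self)
    genera <- c(rep(truth@donorLabel, length(donors)),
                rep("Bacillus", length(self)))
    res <- placementTest(prot[[truth@hgtGeneIds[1]]], panel, genera,
                         "Bacillus")
    expect_true(res$placement_flagged)
    expect_identical(res$placement_taxon, "Brevibacillus")
    # combined screen wires both parts together
    scr <- hgtScreen(genomes(sim)[[s]], truth@hgtCoords,
                     geneSeqs = prot[truth@hgtGeneIds],
                     panel = panel, panelGenera = genera,
                     selfGenus = "Bacillus")
    expect_true(scr$gc$cluster_gc > scr$gc$genome_gc)
    expect_true(all(vapply(scr$placements, `[[`, TRUE,
                           "placement_flagged")))
})
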