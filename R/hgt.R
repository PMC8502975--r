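#' GC content of a nucleotide sequence
#'
#' \code{(G + C) / (A + C + G + T)}; ambiguous bases (N) are excluded from
#' both numerator and denominator, so the value is invariant under reverse
#' complement. Empty or all-N input is an error.
#'
#' @param seq a \code{DNAString}, length-1 \code{DNAStringSet} or character
#'   scalar.
#' @return GC fraction in [0, 1].
#' @examples
#' gcContent("ATGC")    # 0.5
#' gcContent("ATNNAT")  # 0 over the 4 counted bases
#' @export
gcContent <- function(seq) {
    x <- .as_dna(seq, "seq")
    if (length(x) == 0L) .stop_input("empty sequence")
    counts <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
    denom <- sum(counts)
    if (denom == 0L) .stop_input("sequence has no unambiguous bases")
    unname(sum(counts[c("C", "G")]) / denom)
}

#' GC anomaly z-score of a candidate gene cluster
#'
#' Compares the GC content of a genomic interval against the distribution
#' of same-length sliding windows over the whole genome:
#' \code{z = (GC_cluster - mean(GC_windows)) / sd(GC_windows)}. The
#' interval is flagged when |z| meets the threshold (default 2). The
#' original observation this formalizes is graphical (a cluster whose GC
#' visibly exceeds the genomic background), so both the window-based
#' z-score and the plain whole-genome GC are reported.
#'
#' @param genome genome sequence (\code{DNAString} or character).
#' @param start,end cluster coordinates, 0-based half-open; must lie within
#'   the genome, and the cluster must not be longer than the genome.
#' @param step sliding-window step in bp (default: 1/10 of the cluster
#'   length, at least 1).
#' @param threshold |z| at or above which the cluster is flagged.
#' @return list with cluster_gc, genome_gc, background_mean, background_sd,
#'   window_len, step, z_score and gc_flagged.
#' @export
gcZscore <- function(genome, start, end, step = NULL, threshold = 2) {
    g <- .as_dna(genome, "genome")
    len <- length(g)
    if (end <= start || start < 0)
        .stop_input("invalid cluster interval [%d, %d)", start, end)
    if (end - start > len)
        .stop_input("cluster (%d bp) longer than genome (%d bp)",
                    end - start, len)
    if (end > len)
        .stop_input("cluster [%d, %d) outside genome of length %d",
                    start, end, len)
    wl <- end - start
    if (is.null(step)) step <- max(1L, wl %/% 10L)
    cluster_gc <- gcContent(Biostrings::subseq(g, start + 1L, end))
    win_starts <- seq(0L, len - wl, by = step)
    win_gc <- vapply(win_starts, function(s)
        gcContent(Biostrings::subseq(g, s + 1L, s + wl)), 0)
    mu <- mean(win_gc)
    sdev <- sd(win_gc)
    z <- if (sdev > 0) (cluster_gc - mu) / sdev
         else if (abs(cluster_gc - mu) < .Machine$double.eps) 0
         else sign(cluster_gc - mu) * Inf
    list(cluster_gc = cluster_gc, genome_gc = gcContent(g),
         background_mean = mu, background_sd = sdev,
         window_len = wl, step = step, z_score = z,
         gc_flagged = abs(z) >= threshold)
}

#' Gene-tree placement test against a labeled reference panel
#'
#' Builds an NJ tree over the query gene plus a panel of reference proteins
#' labeled by genus, using pairwise global-alignment p-distances, and asks
#' which lineage the query falls into: the placement taxon is the genus of
#' the query's nearest leaf by patristic distance. The gene is flagged as a
#' candidate horizontal transfer when that genus differs from the query's
#' own. A query equidistant from two genera resolves deterministically to
#' the lexicographically first label and is marked as a tie.
#'
#' @param geneSeq query protein sequence (\code{AAString} or character).
#' @param panel named \code{AAStringSet} of reference proteins (>= 3).
#' @param panelGenera character vector of genus labels, one per panel
#'   sequence; at least 2 distinct labels required.
#' @param selfGenus the query's own genus label.
#' @param scoring a [scoringParams()] list.
#' @return list with placement_taxon, placement_flagged, tie, nearest_leaf
#'   and the NJ tree.
#' @export
placementTest <- function(geneSeq, panel, panelGenera, selfGenus,
                          scoring = scoringParams()) {
    if (length(panel) < 3L)
        .stop_input("reference panel needs at least 3 sequences, got %d",
                    length(panel))
    if (length(panelGenera) != length(panel))
        .stop_input("panelGenera must label every panel sequence")
    if (length(unique(panelGenera)) < 2L)
        .stop_input("reference panel needs at least 2 genus labels")
    qname <- "query"
    seqs <- c(setNames(as.character(geneSeq), qname),
              setNames(as.character(panel), names(panel)))
    n <- length(seqs)
    d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        cnt <- .pdist_counts(seqs[[i]], seqs[[j]], scoring)
        d[i, j] <- d[j, i] <- cnt["diff"] / max(cnt["cols"], 1)
    }
    tree <- njTree(d)
    pat <- ape::cophenetic.phylo(tree)
    dq <- pat[qname, setdiff(colnames(pat), qname)]
    near <- names(dq)[dq <= min(dq) + 1e-12]
    genera <- sort(unique(panelGenera[match(near, names(panel))]))
    taxon <- genera[1L]
    list(placement_taxon = taxon,
         placement_flagged = !identical(taxon, selfGenus),
         tie = length(genera) > 1L,
         nearest_leaf = sort(near)[1L],
         tree = tree)
}

#' Screen a gene cluster for horizontal transfer
#'
#' Combines the GC anomaly z-score ([gcZscore()]) of the cluster interval
#' with per-gene placement tests ([placementTest()]) when a labeled
#' reference panel is supplied. Cluster coordinates follow the GFF-lite
#' convention (0-based half-open).
#'
#' @param genome genome sequence.
#' @param clusterGenes data.frame with gene_id, start, end for the cluster
#'   genes (the cluster interval is their bounding range).
#' @param geneSeqs optional \code{AAStringSet} of the cluster genes'
#'   proteins, for the placement test.
#' @param panel,panelGenera,selfGenus see [placementTest()]; ignored when
#'   \code{geneSeqs} is NULL.
#' @param zThreshold |z| threshold for the GC flag.
#' @return list with \code{gc} (the [gcZscore()] result) and
#'   \code{placements} (one placement result per gene, or NULL).
#' @export
hgtScreen <- function(genome, clusterGenes, geneSeqs = NULL, panel = NULL,
                      panelGenera = NULL, selfGenus = "self",
                      zThreshold = 2) {
    gc <- gcZscore(genome, min(clusterGenes$start), max(clusterGenes$end),
                   threshold = zThreshold)
    placements <- NULL
    if (!is.null(geneSeqs) && !is.null(panel)) {
        placements <- lapply(seq_along(geneSeqs), function(i)
            placementTest(geneSeqs[[i]], panel, panelGenera, selfGenus))
        names(placements) <- names(geneSeqs)
    }
    list(gc = gc, placements = placements)
}
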