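#' Cluster similarity hits into ortholog gene families
#'
#' Families are the connected components of the undirected graph whose
#' edges are the threshold-passing hits; genes with no passing edge become
#' singleton families. The construction is transitive: a-b and b-c place
#' a, b and c in one family. Family ids are assigned deterministically as
#' the lexicographically smallest member gene id. Paralogs (several genes
#' from one strain) stay together in one family.
#'
#' The default method is plain connected components, which is deterministic
#' and auditable. A Markov-clustering-style option
#' (\code{method = "mcl"}, inflation 1.5) is provided for sensitivity
#' analysis: it runs expansion/inflation iterations on the column-stochastic
#' pass-graph matrix and takes the support components of the limit matrix,
#' which can split weakly connected components that single linkage would
#' merge.
#'
#' @param hits data.frame of threshold-filtered hits ([allVsAll()]); only
#'   \code{query_id} and \code{subject_id} are used.
#' @param genes data.frame of the full gene universe with columns
#'   \code{gene_id} and \code{strain}; genes without hits are included as
#'   singletons. A hit referencing an id outside the universe is an error.
#' @param method \code{"components"} (default) or \code{"mcl"}.
#' @param inflation MCL inflation exponent (used only for
#'   \code{method = "mcl"}).
#' @return data.frame with columns family_id, strain, gene_id, sorted by
#'   family then gene id. Families partition the gene universe.
#' @seealso [buildMatrix()]
#' @export
clusterFamilies <- function(hits, genes, method = c("components", "mcl"),
                            inflation = 1.5) {
    method <- match.arg(method)
    stopifnot(all(c("gene_id", "strain") %in% names(genes)))
    ids <- genes$gene_id
    if (anyDuplicated(ids))
        .stop_input("duplicate gene id '%s' in universe",
                    ids[which(duplicated(ids))[1L]])
    edge_ids <- c(hits$query_id, hits$subject_id)
    missing <- setdiff(unique(edge_ids), ids)
    if (length(missing))
        .stop_input("hit references gene id '%s' outside the universe",
                    missing[1L])
    comp <- if (method == "mcl" && nrow(hits) > 0) {
        .mcl_membership(ids, hits, inflation)
    } else {
        g <- igraph::graph_from_data_frame(
            d = data.frame(from = hits$query_id, to = hits$subject_id),
            directed = FALSE,
            vertices = data.frame(name = ids))
        igraph::components(g)$membership[ids]
    }
    fam_id <- vapply(split(ids, comp), min, "")[as.character(comp)]
    out <- data.frame(family_id = unname(fam_id), strain = genes$strain,
                      gene_id = ids, stringsAsFactors = FALSE)
    out[order(out$family_id, out$gene_id), , drop = FALSE]
}

# Markov-clustering iteration on the pass graph: expansion (matrix square)
# alternating with inflation (element-wise power, column renormalization)
# until the flow matrix stabilizes; clusters are the support components.
.mcl_membership <- function(ids, hits, inflation, max_iter = 100L,
                            prune = 1e-10) {
    n <- length(ids)
    A <- matrix(0, n, n, dimnames = list(ids, ids))
    qi <- match(hits$query_id, ids)
    si <- match(hits$subject_id, ids)
    A[cbind(qi, si)] <- 1
    A[cbind(si, qi)] <- 1
    diag(A) <- 1
    M <- sweep(A, 2L, colSums(A), "/")
    for (it in seq_len(max_iter)) {
        M2 <- M %*% M
        M2 <- M2^inflation
        M2[M2 < prune] <- 0
        M2 <- sweep(M2, 2L, colSums(M2), "/")
        if (max(abs(M2 - M)) < 1e-8) {
            M <- M2
            break
        }
        M <- M2
    }
    supp <- (M > 0) | t(M > 0)
    g <- igraph::graph_from_adjacency_matrix(supp, mode = "max")
    igraph::components(g)$membership[ids]
}

#' Build the presence-absence matrix from ortholog families
#'
#' Cells are copy counts of each family in each strain; row and column
#' order are the sorted family and strain ids. Column sums equal per-strain
#' gene counts by construction.
#'
#' @param families data.frame from [clusterFamilies()] (family_id, strain,
#'   gene_id).
#' @param strains optional character vector of strain ids to use as columns
#'   (defaults to the strains observed in \code{families}); useful to keep
#'   zero-gene strains as explicit all-zero columns.
#' @return a [PresenceAbsenceMatrix-class].
#' @export
buildMatrix <- function(families, strains = NULL) {
    if (is.null(strains)) strains <- sort(unique(families$strain))
    fams <- sort(unique(families$family_id))
    counts <- table(factor(families$family_id, levels = fams),
                    factor(families$strain, levels = strains))
    m <- matrix(as.integer(counts), nrow = length(fams),
                dimnames = list(fams, strains))
    new("PresenceAbsenceMatrix", counts = m)
}

#' Read and write ortholog family tables and presence-absence matrices
#'
#' Families are stored as a 3-column TSV (family_id, strain, gene_id); the
#' matrix as a TSV with a header row of strain ids and family ids in the
#' first column.
#'
#' @param families data.frame from [clusterFamilies()].
#' @param path file path.
#' @export
writeFamilies <- function(families, path) {
    write.table(families[c("family_id", "strain", "gene_id")], path,
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeFamilies
#' @export
readFamilies <- function(path) {
    read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname writeFamilies
#' @param mat a [PresenceAbsenceMatrix-class].
#' @export
writePresenceAbsence <- function(mat, path) {
    m <- famCounts(mat)
    df <- data.frame(family_id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeFamilies
#' @export
readPresenceAbsence <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- df[[1L]]
    new("PresenceAbsenceMatrix", counts = m)
}
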