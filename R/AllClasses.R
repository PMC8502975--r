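#' @import methods
#' @importFrom stats coef median quantile rbinom rpois runif sd setNames
#' @importFrom utils read.delim write.table head
NULL

setOldClass("phylo")
setClassUnion("listOrNULL", c("list", "NULL"))

#' Configuration of a synthetic strain panel
#'
#' Holds all parameters of the multi-strain simulator: panel size, gene-family
#' model rates, per-branch sequence divergence, nucleotide composition, and the
#' optional planted horizontally transferred cluster.
#'
#' @slot nStrains number of strains (tips of the simulated tree), at least 2.
#' @slot nCore number of single-copy core gene families, at least 1.
#' @slot dispensableRate expected number of family gain events per tree branch
#'   (Poisson mean); gained families are inherited by all descendant tips.
#' @slot uniquePerStrain expected number of strain-specific families per tip
#'   (Poisson mean).
#' @slot geneLenRange closed integer interval of gene lengths in bp
#'   (rounded to whole codons).
#' @slot perBranchDivergence per-site substitution probability applied on
#'   every tree branch.
#' @slot backgroundGC expected GC fraction of the genomic background,
#'   strictly between 0 and 1.
#' @slot spacerLenRange integer interval of intergenic spacer lengths in bp.
#' @slot spacerIndelRate per-branch probability of a short indel in each
#'   intergenic spacer (genes themselves never receive indels).
#' @slot hgtCluster \code{NULL}, or a list with elements \code{n_genes},
#'   \code{gc_shift} and \code{donor_label} describing a contiguous foreign
#'   gene cluster planted into one strain.
#' @slot seed integer seed; identical configuration and seed give
#'   byte-identical output.
#' @seealso [simulationConfig()], [simulateStrains()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(
        nStrains = "integer",
        nCore = "integer",
        dispensableRate = "numeric",
        uniquePerStrain = "numeric",
        geneLenRange = "integer",
        perBranchDivergence = "numeric",
        backgroundGC = "numeric",
        spacerLenRange = "integer",
        spacerIndelRate = "numeric",
        hgtCluster = "listOrNULL",
        seed = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    bad <- function(field, why) sprintf("invalid '%s': %s", field, why)
    msgs <- character()
    if (length(object@nStrains) != 1L || is.na(object@nStrains) ||
        object@nStrains < 2L)
        msgs <- c(msgs, bad("n_strains", "must be a single integer >= 2"))
    if (length(object@nCore) != 1L || is.na(object@nCore) || object@nCore < 1L)
        msgs <- c(msgs, bad("n_core", "must be a single integer >= 1"))
    if (object@dispensableRate < 0)
        msgs <- c(msgs, bad("dispensable_rate", "must be >= 0"))
    if (object@uniquePerStrain < 0)
        msgs <- c(msgs, bad("unique_per_strain", "must be >= 0"))
    if (length(object@geneLenRange) != 2L || any(object@geneLenRange < 30L) ||
        diff(object@geneLenRange) < 0L)
        msgs <- c(msgs, bad("gene_len_range",
                            "must be an increasing interval with min >= 30 bp"))
    if (object@perBranchDivergence < 0 || object@perBranchDivergence >= 1)
        msgs <- c(msgs, bad("per_branch_divergence", "must be in [0, 1)"))
    if (object@backgroundGC <= 0 || object@backgroundGC >= 1)
        msgs <- c(msgs, bad("background_gc", "must be strictly inside (0, 1)"))
    if (length(object@spacerLenRange) != 2L || any(object@spacerLenRange < 1L) ||
        diff(object@spacerLenRange) < 0L)
        msgs <- c(msgs, bad("spacer_len_range", "must be a positive interval"))
    if (object@spacerIndelRate < 0 || object@spacerIndelRate > 1)
        msgs <- c(msgs, bad("spacer_indel_rate", "must be in [0, 1]"))
    if (!is.null(object@hgtCluster)) {
        h <- object@hgtCluster
        need <- c("n_genes", "gc_shift", "donor_label")
        if (!all(need %in% names(h)))
            msgs <- c(msgs, bad("hgt_cluster",
                                "needs n_genes, gc_shift, donor_label"))
        else {
            if (h$n_genes < 1)
                msgs <- c(msgs, bad("hgt_cluster$n_genes", "must be >= 1"))
            gc <- object@backgroundGC + h$gc_shift
            if (gc <= 0 || gc >= 1)
                msgs <- c(msgs, bad("hgt_cluster$gc_shift",
                                    "shifted GC must stay inside (0, 1)"))
        }
    }
    if (length(object@seed) != 1L || is.na(object@seed))
        msgs <- c(msgs, bad("seed", "must be a single integer"))
    if (length(msgs)) msgs else TRUE
})

#' Ground truth of a simulated strain panel
#'
#' @slot tree rooted binary \code{phylo} tree over the strains, branch lengths
#'   equal to the expected substitutions per site on each branch.
#' @slot familyTable true family-by-strain copy-count matrix (planted HGT
#'   genes are tracked separately in \code{hgtGeneIds}).
#' @slot trueAni symmetric matrix of expected pairwise nucleotide identity
#'   (fractions, unit diagonal).
#' @slot hgtGeneIds ids of planted foreign genes (empty if none planted).
#' @slot hgtCoords data.frame with strain, gene_id, start, end (0-based
#'   half-open) of the planted cluster genes.
#' @slot donorSeqs ancestral donor-lineage gene sequences the planted cluster
#'   derives from.
#' @slot donorLabel genus-style label of the donor lineage.
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(
        tree = "phylo",
        familyTable = "matrix",
        trueAni = "matrix",
        hgtGeneIds = "character",
        hgtCoords = "data.frame",
        donorSeqs = "ANY",
        donorLabel = "character"
    )
)

setValidity("GroundTruth", function(object) {
    msgs <- character()
    ta <- object@trueAni
    if (!isTRUE(all.equal(ta, t(ta))))
        msgs <- c(msgs, "trueAni must be symmetric")
    if (nrow(ta) && any(abs(diag(ta) - 1) > 1e-12))
        msgs <- c(msgs, "trueAni must have unit diagonal")
    if (any(object@familyTable < 0))
        msgs <- c(msgs, "familyTable counts must be non-negative")
    if (length(msgs)) msgs else TRUE
})

#' A simulated multi-strain panel with its ground truth
#'
#' Returned by [simulateStrains()]. Use the accessors [proteomes()],
#' [genomes()], [geneTable()], [groundTruth()] and [simConfig()].
#'
#' @slot proteomes named list of \code{AAStringSet}, one per strain.
#' @slot genomes \code{DNAStringSet} of whole-genome sequences, one per strain.
#' @slot geneTable data.frame of gene coordinates: strain, gene_id, start,
#'   end, strand (0-based half-open).
#' @slot truth a [GroundTruth-class] object.
#' @slot config the [SimulationConfig-class] that produced the panel.
#' @exportClass StrainSimulation
setClass("StrainSimulation",
    representation(
        proteomes = "list",
        genomes = "ANY",
        geneTable = "data.frame",
        truth = "GroundTruth",
        config = "SimulationConfig"
    )
)

#' Ortholog family presence-absence matrix
#'
#' Families-by-strains copy-count matrix, the pivot of the pan-genome
#' pipeline. Rows are family ids, columns strain ids, cells non-negative
#' copy counts; all-zero rows are invalid.
#'
#' @slot counts integer matrix with family row names and strain column names.
#' @seealso [buildMatrix()], [panPartition()], [singleCopyCore()]
#' @exportClass PresenceAbsenceMatrix
setClass("PresenceAbsenceMatrix", representation(counts = "matrix"))

setValidity("PresenceAbsenceMatrix", function(object) {
    m <- object@counts
    msgs <- character()
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msgs <- c(msgs, "counts needs family row names and strain column names")
    if (any(m < 0) || any(m != round(m)))
        msgs <- c(msgs, "counts must be non-negative integers")
    if (nrow(m) && any(rowSums(m) == 0))
        msgs <- c(msgs, "all-zero family rows are not allowed")
    if (length(msgs)) msgs else TRUE
})

#' Pan-genome partition counts
#'
#' Family counts of the core / dispensable / strain-specific partition.
#' The identity \code{nPan == nCore + nDispensable + nSpecific} always holds.
#'
#' @slot nPan total number of families.
#' @slot nCore families present in every strain.
#' @slot nDispensable families in at least two but not all strains.
#' @slot nSpecific families in exactly one strain.
#' @slot perStrainSpecific named integer, specific-family count per strain.
#' @exportClass PanPartition
setClass("PanPartition",
    representation(nPan = "integer", nCore = "integer",
                   nDispensable = "integer", nSpecific = "integer",
                   perStrainSpecific = "integer")
)

setValidity("PanPartition", function(object) {
    msgs <- character()
    if (object@nPan != object@nCore + object@nDispensable + object@nSpecific)
        msgs <- c(msgs, "partition identity violated")
    if (sum(object@perStrainSpecific) != object@nSpecific)
        msgs <- c(msgs, "per-strain specific counts must sum to nSpecific")
    if (length(msgs)) msgs else TRUE
})

#' Permutation-sampled pan/core/new-gene curves
#'
#' For each sampled genome ordering and each prefix length x, records the
#' cumulative number of distinct families (pan), the families present in all
#' of the first x strains (core), and the families first seen at step x (new).
#' Medians across orderings are what the regression models are fitted to.
#'
#' @slot pan,core,new data.frames with columns \code{x} and \code{y_median}.
#' @slot samples list of three matrices (orderings x prefix length) of the
#'   per-ordering values.
#' @slot nOrderings number of orderings used (all of them when exhaustive).
#' @slot exhaustive TRUE when every permutation was enumerated.
#' @exportClass PanCurves
setClass("PanCurves",
    representation(pan = "data.frame", core = "data.frame", new = "data.frame",
                   samples = "list", nOrderings = "integer",
                   exhaustive = "logical")
)

#' Heaps-law fit of the pan-genome curve
#'
#' Coefficients of the power-law regression y = A * x^B + C fitted to the
#' pan-curve medians, with the openness verdict: the pan-genome is called
#' open when B lies strictly inside (0, 1), closed otherwise.
#'
#' @slot A,B,C fitted coefficients.
#' @slot rss residual sum of squares of the chosen fit.
#' @slot openness \code{"open"} or \code{"closed"}.
#' @slot converged TRUE when a nonlinear fit converged (FALSE for the
#'   degenerate flat-curve shortcut).
#' @exportClass HeapsFit
setClass("HeapsFit",
    representation(A = "numeric", B = "numeric", C = "numeric",
                   rss = "numeric", openness = "character",
                   converged = "logical")
)

#' Exponential fit of the core-genome curve
#'
#' Coefficients of the exponential regression y = A * exp(B * x) + C fitted
#' to the core-curve medians.
#'
#' @slot A,B,C fitted coefficients.
#' @slot rss residual sum of squares.
#' @slot converged TRUE when a nonlinear fit converged.
#' @exportClass CoreFit
setClass("CoreFit",
    representation(A = "numeric", B = "numeric", C = "numeric",
                   rss = "numeric", converged = "logical")
)

#' Average nucleotide identity matrix
#'
#' Strain-by-strain ANI percentages. The reported value for a pair is the
#' mean of the two directional fragment-based estimates; the diagonal is
#' exactly 100. Pairs for which no fragment survives the 30\%/70\% retention
#' rule are \code{NA} ("undefined", never 0).
#'
#' @slot values numeric matrix of percentages in [0, 100] (or NA).
#' @slot nFragments integer matrix of retained fragment counts per ordered
#'   pair (directional; rows are the fragmented genome).
#' @exportClass AniMatrix
setClass("AniMatrix",
    representation(values = "matrix", nFragments = "matrix")
)

setValidity("AniMatrix", function(object) {
    v <- object@values
    msgs <- character()
    if (nrow(v) && any(abs(diag(v) - 100) > 1e-9))
        msgs <- c(msgs, "diagonal must equal 100")
    off <- v[row(v) != col(v)]
    off <- off[!is.na(off)]
    if (length(off) && (any(off < 0) || any(off > 100)))
        msgs <- c(msgs, "ANI values must lie in [0, 100]")
    if (length(msgs)) msgs else TRUE
})

#' Species grouping from an ANI matrix
#'
#' Partition of the strains into species groups: connected components of the
#' graph with an edge wherever ANI exceeds the threshold (95 by convention).
#'
#' @slot threshold ANI percentage threshold.
#' @slot groups list of character vectors of strain ids, one per group.
#' @exportClass SpeciesGrouping
setClass("SpeciesGrouping",
    representation(threshold = "numeric", groups = "list")
)
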