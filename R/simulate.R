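#' Build a simulation configuration
#'
#' Constructs a validated [SimulationConfig-class]. The defaults describe a
#' small but structured bacterial panel: 8 strains on a random coalescent
#' tree, 20 single-copy core families, tree-structured dispensable gain at 2
#' events per branch, 2 strain-specific families per tip, 1\% per-site
#' substitution per branch and a genomic GC of 41.5\% (a Bacillus-like
#' composition). Genes are whole codons, start with ATG and never contain an
#' internal stop; translation uses the bacterial genetic code (table 11).
#'
#' @param nStrains,nCore,dispensableRate,uniquePerStrain,geneLenRange
#'   gene-family model parameters; see [SimulationConfig-class].
#' @param perBranchDivergence per-site substitution probability per branch.
#' @param backgroundGC expected GC fraction of genes and spacers.
#' @param spacerLenRange,spacerIndelRate intergenic spacer model; indels are
#'   confined to spacers so that true gene identities stay analytic.
#' @param hgtCluster \code{NULL} or \code{list(n_genes=, gc_shift=,
#'   donor_label=)} describing a planted foreign cluster.
#' @param seed integer seed; identical configuration and seed reproduce the
#'   panel byte-for-byte.
#' @return a [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nStrains = 3, nCore = 5, seed = 42)
#' cfg
#' @export
simulationConfig <- function(nStrains = 8L, nCore = 20L,
                             dispensableRate = 2, uniquePerStrain = 2,
                             geneLenRange = c(120L, 300L),
                             perBranchDivergence = 0.01,
                             backgroundGC = 0.415,
                             spacerLenRange = c(80L, 150L),
                             spacerIndelRate = 0.02,
                             hgtCluster = NULL, seed = 1L) {
    new("SimulationConfig",
        nStrains = as.integer(nStrains), nCore = as.integer(nCore),
        dispensableRate = dispensableRate, uniquePerStrain = uniquePerStrain,
        geneLenRange = as.integer(geneLenRange),
        perBranchDivergence = perBranchDivergence,
        backgroundGC = backgroundGC,
        spacerLenRange = as.integer(spacerLenRange),
        spacerIndelRate = spacerIndelRate,
        hgtCluster = hgtCluster, seed = as.integer(seed))
}

# Occupancy layer: tree, family birth events, true family table and true ANI.
# Consumes RNG; callers wrap in .with_seed().
.simulate_occupancy <- function(config) {
    n <- config@nStrains
    strains <- sprintf("S%02d", seq_len(n))
    if (n == 2L) {
        tree <- ape::read.tree(text = "(S01:1,S02:1);")
    } else {
        tree <- ape::rcoal(n, tip.label = strains)
    }
    p <- config@perBranchDivergence
    tree$edge.length <- rep(p, nrow(tree$edge))

    n_edge <- nrow(tree$edge)
    desc_tips <- lapply(seq_len(n_edge), function(e) {
        child <- tree$edge[e, 2L]
        if (child <= n) tree$tip.label[child]
        else ape::extract.clade(tree, child)$tip.label
    })

    fams <- sprintf("F.c%03d", seq_len(config@nCore))
    occupancy <- rep(list(strains), config@nCore)
    births <- rep(0L, config@nCore)             # 0 = born at the root

    if (config@dispensableRate > 0) {
        gains <- rpois(n_edge, config@dispensableRate)
        for (e in seq_len(n_edge)) {
            if (gains[e] == 0L) next
            ids <- sprintf("F.d%02d.%02d", e, seq_len(gains[e]))
            fams <- c(fams, ids)
            occupancy <- c(occupancy, rep(list(desc_tips[[e]]), gains[e]))
            births <- c(births, rep(e, gains[e]))
        }
    }
    if (config@uniquePerStrain > 0) {
        for (s in strains) {
            k <- rpois(1L, config@uniquePerStrain)
            if (k == 0L) next
            ids <- sprintf("F.u.%s.%02d", s, seq_len(k))
            fams <- c(fams, ids)
            occupancy <- c(occupancy, rep(list(s), k))
            births <- c(births, rep(-match(s, strains), k))   # -tip index
        }
    }

    tab <- matrix(0L, length(fams), n, dimnames = list(fams, strains))
    for (i in seq_along(fams)) tab[i, occupancy[[i]]] <- 1L

    tr1 <- tree
    tr1$edge.length <- rep(1, n_edge)
    branches <- ape::cophenetic.phylo(tr1)[strains, strains]
    true_ani <- (1 - p)^branches
    diag(true_ani) <- 1

    list(tree = tree, strains = strains, familyTable = tab,
         births = births, trueAni = true_ani)
}

#' Simulate the family occupancy of a strain panel (no sequences)
#'
#' Runs only the gene-family layer of the simulator: a random coalescent
#' tree, Poisson dispensable-family gains on branches (inherited by all
#' descendant tips) and Poisson strain-specific families per tip. Useful for
#' fast studies of pan-genome curve behaviour where sequences are not
#' needed. The same seed gives the same occupancy that [simulateStrains()]
#' would produce.
#'
#' @param config a [SimulationConfig-class].
#' @return a [GroundTruth-class] with the tree, family table and expected
#'   ANI; no HGT content.
#' @examples
#' truth <- simulateFamilyTable(simulationConfig(nStrains = 4, seed = 7))
#' colSums(truth@familyTable)
#' @export
simulateFamilyTable <- function(config) {
    validObject(config)
    occ <- .with_seed(config@seed, .simulate_occupancy(config))
    new("GroundTruth", tree = occ$tree, familyTable = occ$familyTable,
        trueAni = occ$trueAni, hgtGeneIds = character(),
        hgtCoords = data.frame(), donorSeqs = Biostrings::DNAStringSet(),
        donorLabel = character())
}

# One gene family's sequence bundle: the CDS plus its upstream spacer.
.new_bundle <- function(config, gc = config@backgroundGC) {
    len_bp <- sample(seq(config@geneLenRange[1L], config@geneLenRange[2L]), 1L)
    n_codons <- max(10L, len_bp %/% 3L)
    sp_len <- sample(seq(config@spacerLenRange[1L], config@spacerLenRange[2L]),
                     1L)
    list(gene = .random_cds(n_codons, gc), spacer = .sample_bases(sp_len, gc))
}

.mutate_bundle <- function(b, config) {
    list(gene = .mutate_cds(b$gene, config@perBranchDivergence),
         spacer = .mutate_spacer(b$spacer, config@perBranchDivergence,
                                 config@spacerIndelRate, config@backgroundGC))
}

#' Simulate a multi-strain panel of genomes and proteomes with ground truth
#'
#' Generates \code{nStrains} bacterial strains descending from a known
#' random coalescent tree. Core families are present single-copy in every
#' strain; dispensable families are gained on branches (Poisson per branch)
#' and inherited by all descendant tips; strain-specific families are drawn
#' per tip. Every gene evolves along the tree by independent per-site
#' substitutions at \code{perBranchDivergence} per branch (no indels in
#' genes), so the expected identity between orthologs is
#' \code{(1 - p)^k} over a path of \code{k} branches and the true ANI matrix
#' is known. Genomes are the genes in a canonical family order, interleaved
#' with evolving intergenic spacers at the background GC. If
#' \code{hgtCluster} is configured, a contiguous block of foreign genes with
#' GC shifted by \code{gc_shift} and sequences derived from a separate donor
#' lineage is inserted into exactly one strain's genome; its coordinates and
#' gene ids are recorded in the ground truth and the genes appear in that
#' strain's proteome.
#'
#' @param config a [SimulationConfig-class]; invalid configurations raise an
#'   error naming the offending field.
#' @return a [StrainSimulation-class]; see [proteomes()], [genomes()],
#'   [geneTable()], [groundTruth()].
#' @examples
#' sim <- simulateStrains(simulationConfig(nStrains = 3, nCore = 5, seed = 1))
#' sim
#' names(proteomes(sim))
#' @export
simulateStrains <- function(config) {
    validObject(config)
    .with_seed(config@seed, {
        occ <- .simulate_occupancy(config)
        tree <- occ$tree
        strains <- occ$strains
        n <- length(strains)
        fams <- rownames(occ$familyTable)

        # Families born on each edge (dispensable) or at each tip (unique).
        # Tip numbers in tree$edge index tree$tip.label, which rcoal
        # permutes relative to the strain order, so tips are keyed by label.
        born_on_edge <- split(fams[occ$births > 0L], occ$births[occ$births > 0L])
        born_at_tip <- split(fams[occ$births < 0L],
                             strains[-occ$births[occ$births < 0L]])

        root <- n + 1L
        root_state <- list(TERM = list(gene = character(),
                                       spacer = .sample_bases(
                                           mean(config@spacerLenRange),
                                           config@backgroundGC)))
        for (f in fams[occ$births == 0L]) root_state[[f]] <- .new_bundle(config)

        tip_states <- setNames(vector("list", n), strains)
        walk <- function(node, state) {
            rows <- which(tree$edge[, 1L] == node)
            for (e in rows) {
                child <- tree$edge[e, 2L]
                st <- lapply(state, .mutate_bundle, config = config)
                for (f in born_on_edge[[as.character(e)]])
                    st[[f]] <- .new_bundle(config)
                if (child <= n) {
                    lab <- tree$tip.label[child]
                    for (f in born_at_tip[[lab]])
                        st[[f]] <- .new_bundle(config)
                    tip_states[[lab]] <<- st
                } else {
                    walk(child, st)
                }
            }
        }
        walk(root, root_state)

        # Planted HGT cluster: donor-lineage genes at shifted GC, inserted as
        # one contiguous block into a single recipient strain.
        hgt <- config@hgtCluster
        donor_seqs <- Biostrings::DNAStringSet()
        donor_label <- character()
        hgt_plan <- NULL
        if (!is.null(hgt)) {
            gc_hgt <- config@backgroundGC + hgt$gc_shift
            donors <- lapply(seq_len(hgt$n_genes), function(i)
                .new_bundle(config, gc = gc_hgt))
            planted <- lapply(donors, function(b)
                list(gene = .mutate_cds(b$gene, config@perBranchDivergence),
                     spacer = .sample_bases(length(b$spacer), gc_hgt)))
            recipient <- sample(strains, 1L)
            donor_seqs <- Biostrings::DNAStringSet(
                vapply(donors, function(b) .collapse(b$gene), ""))
            names(donor_seqs) <- sprintf("donor.g%02d", seq_along(donors))
            donor_label <- hgt$donor_label
            hgt_plan <- list(recipient = recipient, planted = planted)
        }

        gene_rows <- list()
        genome_seqs <- character(n)
        prot_list <- vector("list", n)
        hgt_ids <- character()
        hgt_coords <- list()

        for (ti in seq_len(n)) {
            s <- strains[ti]
            st <- tip_states[[s]]
            present <- fams[occ$familyTable[, s] > 0L]
            segs <- lapply(present, function(f)
                list(id = paste0(s, ".", f), bundle = st[[f]], hgt = FALSE))
            if (!is.null(hgt_plan) && hgt_plan$recipient == s) {
                at <- sample(0:length(segs), 1L)
                hgt_segs <- lapply(seq_along(hgt_plan$planted), function(k)
                    list(id = sprintf("%s.hgt%02d", s, k),
                         bundle = hgt_plan$planted[[k]], hgt = TRUE))
                segs <- append(segs, hgt_segs, after = at)
            }
            pieces <- character()
            offset <- 0L
            ids <- character(length(segs))
            prots_src <- vector("list", length(segs))
            for (k in seq_along(segs)) {
                sg <- segs[[k]]
                pieces <- c(pieces, .collapse(sg$bundle$spacer))
                offset <- offset + length(sg$bundle$spacer)
                glen <- length(sg$bundle$gene)
                pieces <- c(pieces, .collapse(sg$bundle$gene))
                gene_rows[[length(gene_rows) + 1L]] <- data.frame(
                    strain = s, gene_id = sg$id, start = offset,
                    end = offset + glen, strand = "+",
                    stringsAsFactors = FALSE)
                if (sg$hgt) {
                    hgt_ids <- c(hgt_ids, sg$id)
                    hgt_coords[[length(hgt_coords) + 1L]] <- data.frame(
                        strain = s, gene_id = sg$id, start = offset,
                        end = offset + glen, stringsAsFactors = FALSE)
                }
                offset <- offset + glen
                ids[k] <- sg$id
                prots_src[[k]] <- sg$bundle$gene
            }
            pieces <- c(pieces, .collapse(st$TERM$spacer))
            genome_seqs[ti] <- paste(pieces, collapse = "")
            prots <- .translate_many(prots_src)
            names(prots) <- ids
            prot_list[[ti]] <- prots
        }

        genomes <- Biostrings::DNAStringSet(genome_seqs)
        names(genomes) <- strains
        names(prot_list) <- strains

        truth <- new("GroundTruth", tree = tree,
                     familyTable = occ$familyTable, trueAni = occ$trueAni,
                     hgtGeneIds = hgt_ids,
                     hgtCoords = if (length(hgt_coords))
                         do.call(rbind, hgt_coords) else data.frame(),
                     donorSeqs = donor_seqs, donorLabel = donor_label)
        new("StrainSimulation", proteomes = prot_list, genomes = genomes,
            geneTable = do.call(rbind, gene_rows), truth = truth,
            config = config)
    })
}

#' Mutate a nucleotide sequence at a fixed per-site substitution rate
#'
#' Each site is substituted independently with probability \code{rate},
#' always to a different base drawn uniformly, so the expected identity to
#' the input is exactly \code{1 - rate}. Used to build genome pairs of known
#' divergence for ANI calibration.
#'
#' @param seq a \code{DNAString}, \code{DNAStringSet} of length 1, or a
#'   character scalar.
#' @param rate per-site substitution probability in [0, 1).
#' @return an object of the same type as \code{seq}.
#' @examples
#' set.seed(1)
#' evolveSequence("ACGTACGTACGT", 0.25)
#' @export
evolveSequence <- function(seq, rate) {
    if (rate < 0 || rate >= 1)
        .stop_input("rate must be in [0, 1), got %g", rate)
    chars_in <- if (is.character(seq)) seq else as.character(seq)
    if (length(chars_in) != 1L)
        .stop_input("evolveSequence expects a single sequence")
    x <- strsplit(chars_in, "")[[1]]
    x <- .substitute_sites(x, rate)
    out <- .collapse(x)
    if (is.character(seq)) out
    else if (methods::is(seq, "DNAStringSet")) Biostrings::DNAStringSet(out)
    else Biostrings::DNAString(out)
}

#' Simulate a clade-structured genome panel for ANI studies
#'
#' Builds \code{nClades * strainsPerClade} genomes from one random ancestor:
#' each clade ancestor diverges from the root at \code{betweenRate}
#' substitutions per site, and each strain diverges from its clade ancestor
#' at \code{withinRate}. Expected pairwise identity is therefore
#' \code{(1 - withinRate)^2} within a clade and roughly
#' \code{(1 - betweenRate)^2 (1 - withinRate)^2} between clades, giving
#' ANI blocks well above and well below the 95\% species boundary at the
#' defaults.
#'
#' @param nClades number of clades.
#' @param strainsPerClade strains per clade.
#' @param withinRate per-site divergence of each strain from its clade
#'   ancestor.
#' @param betweenRate per-site divergence of each clade ancestor from the
#'   root.
#' @param genomeLen genome length in bp.
#' @param gc expected GC fraction.
#' @param seed integer seed.
#' @return list with \code{genomes} (a named \code{DNAStringSet}) and
#'   \code{clades} (named integer vector of true clade labels).
#' @examples
#' panel <- simulateCladePanel(nClades = 2, strainsPerClade = 2,
#'                             genomeLen = 3000, seed = 3)
#' panel$clades
#' @export
simulateCladePanel <- function(nClades = 3L, strainsPerClade = 2L,
                               withinRate = 0.01, betweenRate = 0.10,
                               genomeLen = 6000L, gc = 0.415, seed = 1L) {
    .with_seed(seed, {
        root <- .sample_bases(genomeLen, gc)
        seqs <- character()
        clades <- integer()
        for (cl in seq_len(nClades)) {
            anc <- .substitute_sites(root, betweenRate)
            for (r in seq_len(strainsPerClade)) {
                tip <- .substitute_sites(anc, withinRate)
                seqs <- c(seqs, .collapse(tip))
                clades <- c(clades, cl)
            }
        }
        g <- Biostrings::DNAStringSet(seqs)
        names(g) <- sprintf("C%dS%d", clades,
                            unlist(lapply(seq_len(nClades),
                                          function(i) seq_len(strainsPerClade))))
        names(clades) <- names(g)
        list(genomes = g, clades = clades)
    })
}

#' Write a simulated panel to disk
#'
#' Writes one protein FASTA (\code{<strain>.faa}) and one genome FASTA
#' (\code{<strain>.fna}) per strain, the gene coordinate table
#' (\code{genes.tsv}: strain, gene_id, start, end, strand; 0-based
#' half-open) and the ground truth as JSON (\code{truth.json}: Newick tree,
#' family table, true ANI, planted HGT genes). Identical simulations write
#' byte-identical files.
#'
#' @param sim a [StrainSimulation-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeStrainData <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character()
    for (s in names(proteomes(sim))) {
        faa <- file.path(dir, paste0(s, ".faa"))
        fna <- file.path(dir, paste0(s, ".fna"))
        writeFastaFile(proteomes(sim)[[s]], faa)
        writeFastaFile(genomes(sim)[s], fna)
        paths <- c(paths, faa, fna)
    }
    gtsv <- file.path(dir, "genes.tsv")
    writeGffLite(geneTable(sim), gtsv)
    truth <- groundTruth(sim)
    tj <- file.path(dir, "truth.json")
    jsonlite::write_json(list(
        tree = ape::write.tree(truth@tree),
        family_table = as.data.frame(truth@familyTable),
        families = rownames(truth@familyTable),
        true_ani = as.data.frame(truth@trueAni),
        hgt_gene_ids = truth@hgtGeneIds,
        hgt_coords = truth@hgtCoords,
        donor_label = truth@donorLabel
    ), tj, digits = NA, auto_unbox = TRUE, pretty = TRUE)
    invisible(c(paths, gtsv, tj))
}
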