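# Internal helpers: scoped RNG, nucleotide sampling, mutation machinery.

#' @importFrom stats residuals
NULL

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

# Run code with a fixed seed, restoring the caller's RNG state afterwards.
.with_seed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

# Sample n bases with expected GC equal to gc.
.sample_bases <- function(n, gc) {
    sample(.BASES, n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.codon_of <- function(x, starts) paste0(x[starts], x[starts + 1L], x[starts + 2L])

# Random coding sequence: ATG start, no internal stop codons, GC-weighted.
.random_cds <- function(n_codons, gc) {
    stopifnot(n_codons >= 2)
    x <- .sample_bases(3L * n_codons, gc)
    x[1:3] <- c("A", "T", "G")
    starts <- seq(4L, 3L * n_codons - 2L, by = 3L)
    repeat {
        bad <- starts[.codon_of(x, starts) %in% .STOPS]
        if (!length(bad)) break
        for (s in bad) x[s:(s + 2L)] <- .sample_bases(3L, gc)
    }
    x
}

# For each base (row), the three possible substitution targets.
.ALT <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))

# Substitute each site with probability p, always to a different base.
.substitute_sites <- function(x, p) {
    if (p <= 0 || !length(x)) return(x)
    idx <- which(runif(length(x)) < p)
    if (length(idx)) {
        pick <- sample.int(3L, length(idx), replace = TRUE)
        x[idx] <- .ALT[cbind(match(x[idx], .BASES), pick)]
    }
    x
}

# Mutate a CDS: substitutions, then repair any stop codon created (third
# codon position is rewritten to a base that removes the stop; one always
# exists). The start codon may mutate; only stops are repaired.
.mutate_cds <- function(x, p) {
    if (length(x) < 3L) return(x)
    x <- .substitute_sites(x, p)
    starts <- seq(1L, length(x) - 2L, by = 3L)
    bad <- starts[.codon_of(x, starts) %in% .STOPS]
    for (s in bad) {
        third <- s + 2L
        for (b in sample(setdiff(.BASES, x[third]))) {
            if (!(paste0(x[s], x[s + 1L], b) %in% .STOPS)) {
                x[third] <- b
                break
            }
        }
    }
    x
}

# Mutate an intergenic spacer: substitutions plus, with probability
# indel_rate, one short (1-10 bp) insertion or deletion.
.mutate_spacer <- function(x, p, indel_rate, gc) {
    x <- .substitute_sites(x, p)
    if (indel_rate > 0 && runif(1L) < indel_rate && length(x) > 12L) {
        k <- sample(10L, 1L)
        if (runif(1L) < 0.5) {
            pos <- sample(length(x), 1L)
            x <- append(x, .sample_bases(k, gc), after = pos)
        } else {
            pos <- sample(length(x) - k, 1L)
            x <- x[-(pos:(pos + k - 1L))]
        }
    }
    x
}

.collapse <- function(x) paste(x, collapse = "")

# Translate a character-vector CDS with the bacterial code (table 11).
.translate_many <- function(seqs) {
    dna <- Biostrings::DNAStringSet(vapply(seqs, .collapse, ""))
    Biostrings::translate(dna, genetic.code = Biostrings::getGeneticCode("11"))
}

# All permutations of seq_len(n), in lexicographic order (n small).
.all_perms <- function(n) {
    if (n == 1L) return(list(1L))
    out <- vector("list", factorial(n))
    i <- 0L
    for (first in seq_len(n)) {
        rest <- .all_perms(n - 1L)
        for (r in rest) {
            i <- i + 1L
            tail <- seq_len(n)[-first][r]
            out[[i]] <- c(first, tail)
        }
    }
    out
}

.stop_input <- function(...) {
    stop(structure(class = c("pg_input_error", "error", "condition"),
                   list(message = sprintf(...), call = sys.call(-1))))
}

.stop_fit <- function(...) {
    stop(structure(class = c("pg_fit_error", "error", "condition"),
                   list(message = sprintf(...), call = sys.call(-1))))
}
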