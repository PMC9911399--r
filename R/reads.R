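#' Simulate sequencing reads of the unbound pool
#'
#' Draws `depth` source molecules per concentration multinomially from the
#' unbound-pool composition, attaches a random 2-nt UMI and the library's
#' 3-nt index barcode, duplicates each molecule according to a geometric
#' PCR-duplication distribution, and emits fixed-length DNA reads
#' `UMI + index + constant5 + 7-mer + prefix-of-constant3` with independent
#' per-base substitution errors. Output is deterministic given
#' `config$seed`.
#'
#' @param composition unbound-composition matrix from
#'   [simulate_equilibrium()] (variants x concentrations).
#' @param layout a [construct_layout()].
#' @param config a [simulation_config()]; `config$depth` molecules are
#'   sampled per concentration.
#' @param indexes index barcodes, one per concentration (default
#'   [hitseq_indexes()]).
#' @return A list of class `"read_set"` with elements `reads` (named list
#'   of character vectors of DNA reads, one per library), `molecules`
#'   (matrix of true sampled molecule counts, variants x libraries),
#'   `indexes`, and `concs`.
#' @export
sample_reads <- function(composition, layout = construct_layout(),
                         config = simulation_config(),
                         indexes = hitseq_indexes(ncol(composition))) {
  if (any(composition < 0) || any(colSums(composition) <= 0))
    stop("composition must be nonnegative with positive column sums")
  n_lib <- ncol(composition)
  if (length(indexes) != n_lib)
    stop("need one index barcode per concentration")
  if (config$depth == 0) {
    warning("depth = 0: returning an empty read set")
    empty <- replicate(n_lib, character(0), simplify = FALSE)
    names(empty) <- names(indexes)
    return(structure(list(reads = empty,
                          molecules = matrix(0L, nrow(composition), n_lib,
                                             dimnames = dimnames(composition)),
                          indexes = indexes,
                          concs = colnames(composition)),
                     class = "read_set"))
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  kmer_dna <- rna_to_dna(rownames(composition))
  tail_len <- layout$read_len -
    (layout$umi_len + layout$index_len + nchar(layout$constant5) +
       layout$random_len)
  tail3 <- substr(layout$constant3, 1L, tail_len)
  umis <- all_kmers(layout$umi_len, DNA_BASES)

  reads <- vector("list", n_lib)
  molecules <- matrix(0L, nrow(composition), n_lib,
                      dimnames = dimnames(composition))
  for (j in seq_len(n_lib)) {
    cnt <- as.vector(rmultinom(1L, config$depth,
                               composition[, j] / sum(composition[, j])))
    molecules[, j] <- cnt
    vid <- rep.int(seq_along(cnt), cnt)
    n_mol <- length(vid)
    umi <- umis[sample.int(length(umis), n_mol, replace = TRUE)]
    dup <- if (config$pcr_duplication > 1)
      1L + rgeom(n_mol, 1 / config$pcr_duplication) else rep(1L, n_mol)
    keep <- rep.int(seq_len(n_mol), dup)
    r <- paste0(umi[keep], indexes[[j]], layout$constant5,
                kmer_dna[vid[keep]], tail3)
    if (config$error_rate > 0)
      r <- inject_errors(r, config$error_rate)
    reads[[j]] <- r
  }
  names(reads) <- names(indexes)
  structure(list(reads = reads, molecules = molecules, indexes = indexes,
                 concs = colnames(composition)),
            class = "read_set")
}

## sprinkle independent per-base substitutions over fixed-length reads
inject_errors <- function(reads, rate) {
  len <- nchar(reads[1])
  n_pos <- length(reads) * len
  n_err <- rbinom(1L, n_pos, rate)
  if (n_err == 0L) return(reads)
  pos <- sample.int(n_pos, n_err)
  ri <- (pos - 1L) %/% len + 1L
  pp <- (pos - 1L) %% len + 1L
  cur <- substr(reads[ri], pp, pp)
  # replace with one of the three other bases, uniformly
  shift <- sample.int(3L, n_err, replace = TRUE)
  new <- DNA_BASES[(match(cur, DNA_BASES) - 1L + shift) %% 4L + 1L]
  # substr<- is vectorized but writes to each string once; reads hit by
  # several errors are handled in successive rounds
  while (length(ri)) {
    first <- !duplicated(ri)
    tmp <- reads[ri[first]]
    substr(tmp, pp[first], pp[first]) <- new[first]
    reads[ri[first]] <- tmp
    ri <- ri[!first]; pp <- pp[!first]; new <- new[!first]
  }
  reads
}

#' Write and read simulated reads as FASTQ
#'
#' `write_fastq()` writes a character vector of DNA reads (or all
#' libraries of a `read_set`) as standard 4-line FASTQ records with a
#' constant Sanger quality string; `read_fastq()` reads sequences back.
#' Files with a `.gz` extension are compressed/decompressed transparently.
#'
#' @param reads character vector of DNA reads, or a `read_set` (in which
#'   case one file per library is written and `path` is treated as a
#'   directory).
#' @param path output file (or directory for a `read_set`).
#' @param quality_char single quality character applied to every base.
#' @return `write_fastq()`: the path(s) written, invisibly.
#'   `read_fastq()`: a character vector of sequences.
#' @examples
#' f <- tempfile(fileext = ".fastq")
#' write_fastq(c("ACGT", "GGGG"), f)
#' read_fastq(f)
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  if (inherits(reads, "read_set")) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    files <- file.path(path, paste0(names(reads$reads), ".fastq"))
    for (j in seq_along(files))
      write_fastq(reads$reads[[j]], files[j], quality_char)
    return(invisible(files))
  }
  if (length(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- paste0("read", seq_along(reads))
  q <- Biostrings::BStringSet(strrep(quality_char, nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0L) return(character(0))
  unname(as.character(Biostrings::readDNAStringSet(path, format = "fastq")))
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("HiTS-Eq read set: %d libraries\n", length(x$reads)))
  for (j in seq_along(x$reads))
    cat(sprintf("  %s (index %s, conc %s nM): %d reads\n",
                names(x$reads)[j], x$indexes[[j]], x$concs[j],
                length(x$reads[[j]])))
  invisible(x)
}
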