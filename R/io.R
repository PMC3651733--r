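#' Read a gapped nucleotide alignment from FASTA
#'
#' Sequences are uppercased; `N` is treated as a gap; characters outside
#' `A/C/G/T/-/N` are rejected; all records must have equal length.
#'
#' @param path FASTA file (gaps as `-`).
#' @return Character matrix, one row per record, rows named by record id.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) stop("empty alignment file: ", path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1)
    stop("ragged alignment: record '", names(dna)[which(lens != lens[1])[1]],
         "' has ", lens[lens != lens[1]][1], " sites, expected ", lens[1])
  m <- toupper(do.call(rbind, as.character(dna)))
  rownames(m) <- names(dna)
  bad <- !(m %in% c(BASES, "-", "N"))
  if (any(bad))
    stop("illegal character(s) in alignment: ",
         paste(unique(m[bad]), collapse = ", "))
  m[m == "N"] <- "-"
  m
}

#' Write an alignment to FASTA
#'
#' @param alignment character or integer matrix, rows named.
#' @param path output file.
#' @export
write_alignment <- function(alignment, path) {
  a <- if (is.numeric(alignment)) decode_bases(alignment) else alignment
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(a))) {
    writeLines(paste0(">", rownames(a)[i]), con)
    writeLines(paste(a[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' Read a rooted tree from a Newick file
#'
#' Missing branch lengths are initialized at the prior mean branch length
#' (the hyperprior mean of `mu`, 1.0); duplicate tip labels are rejected.
#'
#' @param path Newick file.
#' @return A rooted `ape::phylo`.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tr <- tryCatch(ape::read.tree(path), error = function(e)
    stop("unparseable Newick file: ", conditionMessage(e)))
  if (is.null(tr)) stop("unparseable Newick file: ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels in tree")
  if (!ape::is.rooted(tr)) stop("tree must be rooted")
  if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

#' Serialize a path trace to CSV (one row per saved value) plus JSON metadata
#'
#' @param trace a `bf_trace`.
#' @param path output CSV path; metadata goes to `<path>.json`.
#' @export
write_trace_csv <- function(trace, path) {
  rows <- do.call(rbind, lapply(seq_along(trace$betas), function(j) {
    m <- trace$samples[[j]]
    data.frame(direction = trace$direction, k = j - 1L,
               beta = trace$betas[j], sample = seq_len(nrow(m)),
               U = m[, "U"], ll0 = m[, "ll0"], ll1 = m[, "ll1"])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  meta <- list(direction = trace$direction, mode = trace$mode,
               K = length(trace$betas) - 1L, Q = trace$Q,
               save_interval = trace$save_interval,
               kind = trace$schedule$kind,
               alpha = trace$schedule$alpha)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

interval_seed <- function(base_seed, interval, direction) {
  as.integer((base_seed + 7919 * interval +
                104729 * (direction == "melting")) %% 2147483647)
}
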