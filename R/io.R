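## Readers and writers: fragments/pairs TSV (5C), dense count matrix TSV
## (Hi-C), coarse-grained PDB ensembles with a manifest.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

check_numeric_col <- function(df, col, path) {
  x <- df[[col]]
  if (is.null(x))
    stop(path, ": missing required column '", col, "'", call. = FALSE)
  num <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(num) & !is.na(x))
  if (length(bad))
    stop(sprintf("%s: non-numeric value '%s' in column '%s', line %d",
                 path, x[bad[1L]], col, bad[1L] + 1L), call. = FALSE)
  num
}

#' Read an interaction dataset from disk
#'
#' 5C mode: a fragments TSV (columns `id`, `chrom`, `start`, `end`;
#' 0-based half-open coordinates) plus a pairs TSV (columns `frag_i`,
#' `frag_j`, `if_value`, `sigma`).  Hi-C mode: the fragments TSV plus a
#' dense count matrix TSV whose header carries `chrom:start-end` bin
#' labels; `NA` cells mark unmeasured pairs.  Validation failures name
#' the offending line.
#'
#' @param fragments_path Path to the fragments TSV.
#' @param pairs_path Path to the 5C pairs TSV (5C mode).
#' @param matrix_path Path to the Hi-C matrix TSV (Hi-C mode).
#' @param technology `"5C"` or `"HiC"`.
#' @return An [if_dataset()].
#' @export
read_dataset <- function(fragments_path, pairs_path = NULL,
                         matrix_path = NULL,
                         technology = c("5C", "HiC")) {
  technology <- match.arg(technology)
  fr <- read_tsv_checked(fragments_path)
  fmap <- fragment_map(chrom = fr$chrom,
                       start = check_numeric_col(fr, "start", fragments_path),
                       end = check_numeric_col(fr, "end", fragments_path),
                       id = check_numeric_col(fr, "id", fragments_path))
  n <- nrow(fmap)
  if (technology == "5C") {
    if (is.null(pairs_path))
      stop("5C datasets need pairs_path", call. = FALSE)
    pt <- read_tsv_checked(pairs_path)
    i <- check_numeric_col(pt, "frag_i", pairs_path)
    j <- check_numeric_col(pt, "frag_j", pairs_path)
    v <- check_numeric_col(pt, "if_value", pairs_path)
    s <- check_numeric_col(pt, "sigma", pairs_path)
    bad <- which(i < 1 | i > n | j < 1 | j > n)
    if (length(bad))
      stop(sprintf("%s: line %d references unknown fragment id %d (of %d)",
                   pairs_path, bad[1L] + 1L,
                   max(i[bad[1L]], j[bad[1L]]), n), call. = FALSE)
    key <- paste(pmin(i, j), pmax(i, j))
    if (anyDuplicated(key)) {
      dup <- which(duplicated(key))[1L]
      stop(sprintf("%s: duplicate pair (%d, %d) at line %d",
                   pairs_path, i[dup], j[dup], dup + 1L), call. = FALSE)
    }
    if_dataset(fmap, data.frame(i = i, j = j, value = v, sigma = s),
               technology = "5C")
  } else {
    if (is.null(matrix_path))
      stop("Hi-C datasets need matrix_path", call. = FALSE)
    m <- as.matrix(utils::read.delim(matrix_path, row.names = 1L,
                                     check.names = FALSE))
    if (nrow(m) != n || ncol(m) != n)
      stop(matrix_path, ": matrix dimension does not match the fragment map",
           call. = FALSE)
    if (any(!is.na(m) & is.na(suppressWarnings(matrix(as.numeric(m),
                                                      nrow(m))))))
      stop(matrix_path, ": non-numeric matrix entry", call. = FALSE)
    ut <- which(upper.tri(m), arr.ind = TRUE)
    keep <- !is.na(m[ut])
    if_dataset(fmap, data.frame(i = ut[keep, 1L], j = ut[keep, 2L],
                                value = m[ut][keep], sigma = NA_real_),
               technology = "HiC")
  }
}

#' Write an interaction dataset to disk
#'
#' Inverse of [read_dataset()]; decimal text round-trips exactly at
#' `format` precision (17 significant digits).
#'
#' @param data [if_dataset()].
#' @param fragments_path Output path for the fragments TSV.
#' @param pairs_path Output path for the 5C pairs TSV.
#' @param matrix_path Output path for the Hi-C matrix TSV.
#' @return Invisibly, the dataset.
#' @export
write_dataset <- function(data, fragments_path, pairs_path = NULL,
                          matrix_path = NULL) {
  fr <- as.data.frame(data$fragments)
  utils::write.table(fr, fragments_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p <- data$pairs
  if (data$technology == "5C") {
    if (is.null(pairs_path)) stop("need pairs_path for 5C", call. = FALSE)
    out <- data.frame(frag_i = p$i, frag_j = p$j,
                      if_value = format(p$value, digits = 17,
                                        scientific = TRUE, trim = TRUE),
                      sigma = format(p$sigma, digits = 17,
                                     scientific = TRUE, trim = TRUE))
    utils::write.table(out, pairs_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    if (is.null(matrix_path)) stop("need matrix_path for Hi-C", call. = FALSE)
    n <- nrow(fr)
    m <- matrix(NA_real_, n, n)
    m[cbind(p$i, p$j)] <- p$value
    m[cbind(p$j, p$i)] <- p$value
    diag(m) <- 0
    labs <- sprintf("%s:%d-%d", fr$chrom, fr$start, fr$end)
    dimnames(m) <- list(labs, labs)
    utils::write.table(m, matrix_path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(data)
}

## ---- PDB ------------------------------------------------------------------

pdb_scale_factor <- function(structures, scale_policy) {
  maxabs <- max(abs(unlist(lapply(structures, range))))
  s <- switch(scale_policy,
              nm_to_angstrom = 10,
              none = 1,
              auto = 10)
  if (maxabs * s > 999.999) s <- 999.0 / maxabs  # keep inside the 8.3 field
  s
}

write_structure_pdb <- function(conf, path, scale, log_posterior = NA) {
  n <- nrow(conf)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   3 SCALE_FACTOR %.10g", scale), con)
  writeLines(sprintf("REMARK   3 LOG_POSTERIOR %.12g", log_posterior), con)
  xyz <- conf * scale
  lines <- sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), seq_len(n), xyz[, 1L], xyz[, 2L], xyz[, 3L])
  writeLines(lines, con)
  writeLines("END", con)
  invisible(path)
}

#' Export an ensemble as PDB files plus a manifest
#'
#' One PDB per member: each fragment is a single CA pseudo-atom with
#' residue number equal to the fragment index, on chain A.  Coordinates
#' are uniformly rescaled (nm to Angstrom by default, shrunk further if
#' needed to fit the fixed-width 8.3 field); the scale factor and log
#' posterior are recorded as REMARK records, so original coordinates are
#' recoverable to field precision.  `manifest.tsv` lists file, chain,
#' iteration and log posterior; the fragment map is written alongside so
#' a directory is self-contained ([read_ensemble_pdb()]).
#'
#' @param ens A `conf_ensemble`.
#' @param out_dir Output directory (created if needed).
#' @param scale_policy `"nm_to_angstrom"` (default), `"auto"`, `"none"`.
#' @return Invisibly, the manifest data frame.
#' @export
write_ensemble_pdb <- function(ens, out_dir,
                               scale_policy = c("nm_to_angstrom", "auto",
                                                "none")) {
  scale_policy <- match.arg(scale_policy)
  if (length(ens$structures) == 0) stop("empty ensemble", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scale <- pdb_scale_factor(ens$structures, scale_policy)
  files <- sprintf("structure_%03d.pdb", seq_along(ens$structures))
  for (s in seq_along(ens$structures))
    write_structure_pdb(ens$structures[[s]], file.path(out_dir, files[s]),
                        scale, ens$log_posterior[s])
  manifest <- data.frame(file = files, chain = ens$chain,
                         iteration = ens$iteration,
                         log_posterior = ens$log_posterior)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ens$fragments))
    utils::write.table(as.data.frame(ens$fragments),
                       file.path(out_dir, "fragments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a single coarse-grained PDB structure
#'
#' Parses ATOM records (fixed-width columns) and the SCALE_FACTOR /
#' LOG_POSTERIOR REMARKs written by [write_ensemble_pdb()]; coordinates
#' are returned in original model units (divided by the scale factor).
#'
#' @param path PDB file path.
#' @return `list(conformation, log_posterior, scale)`.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  scale <- 1; lp <- NA_real_
  sc <- grep("^REMARK   3 SCALE_FACTOR", lines, value = TRUE)
  if (length(sc)) scale <- as.numeric(sub(".*SCALE_FACTOR ", "", sc[1L]))
  lpl <- grep("^REMARK   3 LOG_POSTERIOR", lines, value = TRUE)
  if (length(lpl)) lp <- as.numeric(sub(".*LOG_POSTERIOR ", "", lpl[1L]))
  at <- lines[substr(lines, 1L, 6L) %in% c("ATOM  ", "HETATM")]
  if (!length(at)) stop(path, ": no ATOM records", call. = FALSE)
  xyz <- cbind(as.numeric(substr(at, 31L, 38L)),
               as.numeric(substr(at, 39L, 46L)),
               as.numeric(substr(at, 47L, 54L)))
  list(conformation = xyz / scale, log_posterior = lp, scale = scale,
       residue = as.integer(substr(at, 23L, 26L)))
}

#' Read back an ensemble directory written by [write_ensemble_pdb()]
#'
#' @param dir Directory containing `manifest.tsv` and the PDB files.
#' @return A `conf_ensemble`.
#' @export
read_ensemble_pdb <- function(dir) {
  manifest <- read_tsv_checked(file.path(dir, "manifest.tsv"))
  structures <- lapply(file.path(dir, manifest$file),
                       function(f) read_pdb(f)$conformation)
  fragments <- NULL
  fp <- file.path(dir, "fragments.tsv")
  if (file.exists(fp)) {
    fr <- read_tsv_checked(fp)
    fragments <- fragment_map(fr$chrom, fr$start, fr$end, fr$id)
  }
  structure(list(structures = structures,
                 log_posterior = manifest$log_posterior,
                 chain = manifest$chain, iteration = manifest$iteration,
                 fragments = fragments),
            class = "conf_ensemble")
}

write_run_config <- function(path, values) {
  lines <- vapply(names(values),
                  function(k) sprintf("%s=%s", k,
                                      paste(format(values[[k]]),
                                            collapse = ",")),
                  character(1L))
  writeLines(lines, path)
  invisible(path)
}
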