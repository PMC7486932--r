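#' Read a chunklengths (coancestry) matrix
#'
#' Parses the whitespace-delimited chunklength dialect produced by haplotype
#' painting: a header row beginning `Recipient` followed by donor ids, then
#' one row per recipient (id then donated cM per donor column). Entry (i, j)
#' is the genetic length donor j donates to recipient i. Ids are
#' case-sensitive exact strings.
#'
#' @param path path to the file.
#' @return square numeric matrix with recipient/donor ids as dimnames and a
#'   zero diagonal (a nonzero diagonal is zeroed with a warning).
#' @export
read_chunklengths <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("chunklengths file has no data rows",
                              call. = FALSE)
  header <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  donors <- header[-1]
  if (anyDuplicated(donors) > 0)
    stop("duplicate donor ids in header: ",
         paste(unique(donors[duplicated(donors)]), collapse = ", "),
         call. = FALSE)
  n <- length(donors)
  m <- matrix(NA_real_, length(lines) - 1, n)
  ids <- character(length(lines) - 1)
  for (k in seq_along(ids)) {
    fields <- strsplit(trimws(lines[k + 1]), "[ \t]+")[[1]]
    if (length(fields) != n + 1)
      stop(sprintf("line %d: expected %d fields, found %d", k + 1, n + 1,
                   length(fields)), call. = FALSE)
    ids[k] <- fields[1]
    vals <- suppressWarnings(as.numeric(fields[-1]))
    if (anyNA(vals))
      stop(sprintf("line %d: non-numeric cell for recipient '%s'", k + 1,
                   ids[k]), call. = FALSE)
    m[k, ] <- vals
  }
  if (anyDuplicated(ids) > 0)
    stop("duplicate recipient ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (!setequal(ids, donors)) {
    bad <- c(setdiff(ids, donors), setdiff(donors, ids))
    stop("recipient/donor id sets differ; offending id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- m[, match(ids, donors), drop = FALSE]
  dimnames(m) <- list(ids, ids)
  if (any(diag(m) != 0)) {
    warning("nonzero diagonal entries set to 0 (painting never self-copies)")
    diag(m) <- 0
  }
  m
}

#' Write a chunklengths matrix
#'
#' Inverse of [read_chunklengths()]: header row `Recipient` plus donor ids,
#' then one space-delimited row per recipient. Values are written with full
#' precision so a round trip is bit-equal.
#'
#' @param m square matrix with id dimnames.
#' @param path output path.
#' @export
write_chunklengths <- function(m, path) {
  ids <- rownames(m)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("Recipient", ids), collapse = " "), con)
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(ids[i], format(m[i, ], digits = 17, trim = TRUE,
                           scientific = FALSE)), collapse = " "),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read an IBD segment file
#'
#' Parses the 9-column tab-delimited segment dialect of RefinedIBD output:
#' sample1, hap1, sample2, hap2, chromosome, start_bp, end_bp, LOD,
#' length_cM. Pairs are canonicalised so `id1 < id2`; self-pairs and
#' malformed rows are rejected with their line numbers.
#'
#' @param path path to the file.
#' @return data frame with columns id1, id2, chromosome, start_bp, end_bp,
#'   length_cM, lod.
#' @export
read_ibd <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_ibd()[, 1:7])
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols != 9))
    stop("line(s) ", paste(which(ncols != 9), collapse = ", "),
         ": expected 9 tab-delimited columns", call. = FALSE)
  tab <- do.call(rbind, parts)
  num <- suppressWarnings(apply(tab[, c(5, 6, 7, 8, 9), drop = FALSE], 2,
                                as.numeric))
  num <- matrix(num, ncol = 5)
  bad <- which(rowSums(is.na(num)) > 0)
  if (length(bad) > 0)
    stop("line(s) ", paste(bad, collapse = ", "),
         ": non-numeric coordinate/score fields", call. = FALSE)
  self <- which(tab[, 1] == tab[, 3])
  if (length(self) > 0)
    stop("line(s) ", paste(self, collapse = ", "),
         ": self-pair (sample1 == sample2)", call. = FALSE)
  if (any(num[, 2] >= num[, 3]))
    stop("line(s) ", paste(which(num[, 2] >= num[, 3]), collapse = ", "),
         ": start_bp must be < end_bp", call. = FALSE)
  if (any(num[, 5] <= 0))
    stop("line(s) ", paste(which(num[, 5] <= 0), collapse = ", "),
         ": length_cM must be > 0", call. = FALSE)
  seg <- data.frame(id1 = tab[, 1], id2 = tab[, 3],
                    chromosome = as.integer(num[, 1]),
                    start_bp = num[, 2], end_bp = num[, 3],
                    length_cM = num[, 5], lod = num[, 4],
                    stringsAsFactors = FALSE)
  canonicalize_pairs(seg)
}

#' Write an IBD segment file
#'
#' Writes the 9-column RefinedIBD-format dialect read by [read_ibd()].
#' Haplotype indices are written as 1 and the LOD column from the `lod`
#' field (10.0 for synthetic segments).
#'
#' @param segments IBD segment data frame.
#' @param path output path.
#' @export
write_ibd <- function(segments, path) {
  lod <- if ("lod" %in% names(segments)) segments$lod else 10.0
  rows <- sprintf("%s\t1\t%s\t1\t%d\t%.0f\t%.0f\t%s\t%s",
                  segments$id1, segments$id2,
                  as.integer(segments$chromosome),
                  segments$start_bp, segments$end_bp,
                  format(lod, digits = 17, trim = TRUE, scientific = FALSE),
                  format(segments$length_cM, digits = 17, trim = TRUE,
                         scientific = FALSE))
  writeLines(rows, path)
  invisible(path)
}

#' Write all cohort artefacts to a directory
#'
#' Writes `chunklengths.txt` (painting dialect), `ibd.txt` (RefinedIBD
#' dialect), `geography.tsv` (id, longitude, latitude, town, province) and
#' `truth.tsv` (id, deme, true share per source, phenotype).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_chunklengths(cohort$coancestry, file.path(dir, "chunklengths.txt"))
  write_ibd(cohort$ibd, file.path(dir, "ibd.txt"))
  utils::write.table(cohort$individuals[, c("id", "longitude", "latitude",
                                            "town", "province")],
                     file.path(dir, "geography.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- data.frame(id = cohort$individuals$id,
                      deme = cohort$individuals$deme,
                      cohort$true_ancestry,
                      phenotype = cohort$phenotype[cohort$individuals$id],
                      check.names = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
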