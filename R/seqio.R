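#' Validate and normalise a raw amino-acid sequence
#'
#' Uppercases the input and resolves non-standard letters. Under
#' `"map-ambiguous"` (the default) the common ambiguity codes are mapped to a
#' standard residue (B to D, Z to E, U to C) and every other non-standard
#' letter (X, J, O, `*`, gaps, ...) is dropped. Under `"strict"` any character
#' outside the 20 standard letters is an error.
#'
#' @param raw Character scalar, the raw sequence.
#' @param policy `"map-ambiguous"` or `"strict"`.
#' @return Character scalar over the 20 standard amino-acid letters.
#' @examples
#' validate_sequence("acDE")          # "ACDE"
#' validate_sequence("AXC")           # "AC"
#' @export
validate_sequence <- function(raw, policy = c("map-ambiguous", "strict")) {
  policy <- match.arg(policy)
  if (!is.character(raw) || length(raw) != 1 || is.na(raw) || !nzchar(raw)) {
    stop("`raw` must be a non-empty character scalar", call. = FALSE)
  }
  s <- toupper(gsub("[[:space:]]", "", raw))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% AA_ORDER)
  if (policy == "strict") {
    if (any(bad)) {
      stop("non-standard residue(s) in sequence: ",
           paste(unique(chars[bad]), collapse = ", "), call. = FALSE)
    }
    return(s)
  }
  map <- c(B = "D", Z = "E", U = "C")
  chars[bad] <- ifelse(chars[bad] %in% names(map), map[chars[bad]], "")
  out <- paste(chars, collapse = "")
  if (!nzchar(out)) {
    stop("sequence empty after removing non-standard residues", call. = FALSE)
  }
  out
}

#' Read protein records from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file into a tibble of
#' protein records. The record id is the first whitespace-delimited token of
#' the header; sequences are normalised through [validate_sequence()].
#'
#' @param path Path to a FASTA file.
#' @param label Optional label for every record: a single 0/1 value, or a
#'   named vector / two-column data frame (`id`, `label`) mapping ids to 0/1.
#' @param policy Sequence validation policy, see [validate_sequence()].
#' @return A tibble with columns `id`, `sequence` and (if labels were given)
#'   `label`; zero rows for an empty file.
#' @export
read_fasta <- function(path, label = NULL, policy = "map-ambiguous") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    return(tibble::tibble(id = character(), sequence = character()))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA in ", path, ": line ", nonblank[1],
         " does not start a record header", call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1)
  if (any(!nzchar(ids))) {
    stop("malformed FASTA in ", path, ": empty record id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- vapply(as.character(set), validate_sequence, "",
                 policy = policy, USE.NAMES = FALSE)
  out <- tibble::tibble(id = ids, sequence = seqs)
  if (!is.null(label)) out$label <- resolve_labels(label, ids)
  out
}

resolve_labels <- function(label, ids) {
  if (is.data.frame(label)) {
    lab <- stats::setNames(label[[2]], label[[1]])
  } else if (!is.null(names(label)) && length(label) > 1) {
    lab <- label
  } else {
    lab <- stats::setNames(rep(label, length(ids)), ids)
  }
  missing <- setdiff(ids, names(lab))
  if (length(missing)) {
    stop("no label for record(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- as.integer(lab[ids])
  if (!all(out %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  out
}

#' Write protein records to a FASTA file
#'
#' @param records Tibble with `id` and `sequence` columns.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  set <- Biostrings::BStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a two-column id/label table
#'
#' @param path Path to a headered TSV with columns `id` and `label` (0/1).
#' @return Tibble with `id` (character) and `label` (integer).
#' @export
read_label_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = c("character", "integer"))
  names(tab) <- c("id", "label")
  if (!all(tab$label %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  tibble::as_tibble(tab)
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the `-out_ascii_pssm` dialect: two header lines, then one row per
#' position holding the position index, the residue, and at least 20 integer
#' log-odds scores. Trailing columns (weighted percentages, information
#' content, relative weight) are ignored; only the first 20 score columns are
#' kept, in PSI-BLAST column order (A R N D C Q E G H I L K M F P S T W Y V).
#'
#' @param path Path to the ASCII PSSM file.
#' @param record_id Id to attach; defaults to the file name without extension.
#' @return A `pssm_profile`: list with `record_id`, `residues` (length-L
#'   string) and `scores` (L x 20 numeric matrix, PSI-BLAST column order).
#' @export
read_pssm <- function(path, record_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rows <- grep("^\\s*[0-9]+\\s+[A-Za-z]\\s", lines)
  if (length(rows) == 0) {
    stop("no PSSM rows found in ", path, call. = FALSE)
  }
  parts <- strsplit(trimws(lines[rows]), "\\s+")
  nfield <- lengths(parts)
  if (any(nfield < 22)) {
    stop("PSSM parse error in ", path, ": line ", rows[which(nfield < 22)[1]],
         " has fewer than 20 score columns", call. = FALSE)
  }
  residues <- vapply(parts, `[`, "", 2)
  scores <- t(vapply(parts, function(p) as.numeric(p[3:22]), numeric(20)))
  if (anyNA(scores)) {
    stop("PSSM parse error in ", path, ": non-numeric score", call. = FALSE)
  }
  colnames(scores) <- PSSM_COL_ORDER
  new_pssm_profile(
    record_id = record_id %||% sub("\\.[^.]*$", "", basename(path)),
    residues = paste(residues, collapse = ""),
    scores = scores
  )
}

new_pssm_profile <- function(record_id, residues, scores) {
  if (nrow(scores) != nchar(residues)) {
    stop("PSSM residue string length (", nchar(residues),
         ") does not match score row count (", nrow(scores), ")",
         call. = FALSE)
  }
  if (ncol(scores) != 20) stop("PSSM must have 20 score columns", call. = FALSE)
  if (nrow(scores) == 0) stop("empty PSSM", call. = FALSE)
  structure(list(record_id = record_id, residues = residues, scores = scores),
            class = "pssm_profile")
}

#' Write a PSSM profile in PSI-BLAST ASCII format
#'
#' @param profile A `pssm_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  res <- strsplit(profile$residues, "")[[1]]
  header <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("            ", paste(sprintf("%3s", PSSM_COL_ORDER), collapse = " "))
  )
  body <- vapply(seq_along(res), function(i) {
    paste0(sprintf("%5d %s  ", i, res[i]),
           paste(sprintf("%3d", as.integer(round(profile$scores[i, ]))),
                 collapse = " "))
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat("<pssm_profile> ", x$record_id, ": ", nrow(x$scores),
      " positions x 20 scores\n", sep = "")
  invisible(x)
}

#' Read per-record PSSM profiles from a directory
#'
#' Looks for `<id>.pssm` in `dir` for every record id.
#'
#' @param records Tibble with an `id` column.
#' @param dir Directory holding `<id>.pssm` files.
#' @return Named list of `pssm_profile`, one per record.
#' @export
read_pssm_dir <- function(records, dir) {
  paths <- file.path(dir, paste0(records$id, ".pssm"))
  missing <- records$id[!file.exists(paths)]
  if (length(missing)) {
    stop("missing PSSM file(s) for record(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...", call. = FALSE)
  }
  stats::setNames(
    purrr::map2(paths, records$id, ~ read_pssm(.x, record_id = .y)),
    records$id
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
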