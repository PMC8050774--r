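#' Column maps for search-engine result tables
#'
#' The pipeline reads tab-separated result tables in the MaxQuant-style
#' dialect ("Sequence", "Intensity H", "Reverse", ...). Column names are
#' configuration, not hard-coded: every reader takes a map from internal
#' field names to the header names present in the file, so other dialects
#' can be adapted without code changes.
#'
#' @param ... header names overriding the defaults, given as
#'   `internal_name = "Header Name"`.
#' @return Named character vector mapping internal field names to headers.
#' @export
evidence_columns <- function(...) {
  map <- c(
    peptide_sequence = "Sequence",
    charge           = "Charge",
    intensity_heavy  = "Intensity H",
    intensity_light  = "Intensity L",
    protein_group_id = "Protein group IDs",
    raw_file         = "Raw file",
    fraction         = "Fraction",
    replicate_bio    = "Bio replicate",
    replicate_tech   = "Tech replicate",
    timepoint_days   = "Timepoint [days]",
    modifications    = "Modifications"
  )
  .override_map(map, list(...))
}

#' @rdname evidence_columns
#' @export
protein_group_columns <- function(...) {
  map <- c(
    protein_group_id     = "Protein group IDs",
    member_protein_ids   = "Protein IDs",
    ratio_hl_normalized  = "Ratio H/L normalized",
    intensity_heavy      = "Intensity H",
    intensity_light      = "Intensity L",
    flag_reverse         = "Reverse",
    flag_contaminant     = "Potential contaminant",
    flag_only_by_site    = "Only identified by site"
  )
  .override_map(map, list(...))
}

#' @rdname evidence_columns
#' @export
site_columns <- function(...) {
  map <- c(
    protein_group_id     = "Protein group IDs",
    position             = "Position",
    residue              = "Amino acid",
    localization_prob    = "Localization prob",
    intensity_heavy      = "Intensity H",
    intensity_light      = "Intensity L"
  )
  .override_map(map, list(...))
}

.override_map <- function(map, over) {
  if (length(over)) {
    bad <- setdiff(names(over), names(map))
    if (length(bad))
      stop("unknown column-map field(s): ", paste(bad, collapse = ", "))
    map[names(over)] <- unlist(over)
  }
  map
}

# Prefix used for per-replicate site ratio columns, e.g.
# "Ratio H/L normalized b1t2" -> internal "ratio_hl.b1t2".
.SITE_RATIO_PREFIX <- "Ratio H/L normalized "

#' @keywords internal
replicate_label <- function(bio, tech) sprintf("b%dt%d", bio, tech)

#' @keywords internal
parse_replicate_label <- function(label) {
  m <- regmatches(label, regexec("^b([0-9]+)t([0-9]+)$", label))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed replicate label(s): ", paste(label[bad], collapse = ", "))
  data.frame(
    label = label,
    replicate_bio  = vapply(m, function(x) as.integer(x[2]), 1L),
    replicate_tech = vapply(m, function(x) as.integer(x[3]), 1L),
    stringsAsFactors = FALSE
  )
}

.read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          na.strings = NULL, quote = "", stringsAsFactors = FALSE)
  df
}

.require_columns <- function(df, map, required, path) {
  missing <- required[!(map[required] %in% names(df))]
  if (length(missing))
    stop(sprintf("format error in '%s': missing mandatory column(s): %s",
                 path, paste(sprintf("'%s'", map[missing]), collapse = ", ")))
}

# Parse a character column to numeric; empty cells become NA (never 0);
# unparsable cells raise an error naming the column and the file line
# (header = line 1, so data row i is line i + 1).
.parse_numeric <- function(x, col_label, path) {
  x <- trimws(x)
  x[!nzchar(x)] <- NA_character_
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(v))
  if (length(bad))
    stop(sprintf("row-level error in '%s', line %d: unparsable numeric '%s' in column '%s'",
                 path, bad[1] + 1L, x[bad[1]], col_label))
  v
}

.parse_flag <- function(x) {
  x <- trimws(x)
  x == "+"
}

.get_chr <- function(df, map, field, default = NA_character_) {
  hdr <- map[[field]]
  if (!is.null(hdr) && hdr %in% names(df)) trimws(df[[hdr]])
  else rep(default, nrow(df))
}

.get_num <- function(df, map, field, path, default = NA_real_) {
  hdr <- map[[field]]
  if (!is.null(hdr) && hdr %in% names(df)) .parse_numeric(df[[hdr]], hdr, path)
  else rep(default, nrow(df))
}

.AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read a peptide evidence table
#'
#' One row per quantified peptide observation with heavy/light intensities.
#' Absent intensities are parsed as `NA`, never as 0; every row must carry
#' at least one of the two channel intensities.
#'
#' @param path path to a tab-separated evidence table.
#' @param columns column map, see [evidence_columns()].
#' @return A data.frame with internal column names (`peptide_sequence`,
#'   `charge`, `intensity_heavy`, `intensity_light`, `protein_group_id`,
#'   `raw_file`, `fraction`, `replicate_bio`, `replicate_tech`,
#'   `timepoint_days`, `modifications`).
#' @export
read_evidence <- function(path, columns = evidence_columns()) {
  df <- .read_tsv_raw(path)
  .require_columns(df, columns,
                   c("peptide_sequence", "charge", "intensity_heavy",
                     "intensity_light", "protein_group_id"), path)
  out <- data.frame(
    peptide_sequence = .get_chr(df, columns, "peptide_sequence"),
    charge           = as.integer(.get_num(df, columns, "charge", path)),
    intensity_heavy  = .get_num(df, columns, "intensity_heavy", path),
    intensity_light  = .get_num(df, columns, "intensity_light", path),
    protein_group_id = .get_chr(df, columns, "protein_group_id"),
    raw_file         = .get_chr(df, columns, "raw_file"),
    fraction         = as.integer(.get_num(df, columns, "fraction", path, 0)),
    replicate_bio    = as.integer(.get_num(df, columns, "replicate_bio", path, 1)),
    replicate_tech   = as.integer(.get_num(df, columns, "replicate_tech", path, 1)),
    timepoint_days   = .get_num(df, columns, "timepoint_days", path),
    modifications    = .get_chr(df, columns, "modifications", ""),
    stringsAsFactors = FALSE
  )
  bad_seq <- which(!nzchar(out$peptide_sequence) |
                     !grepl(sprintf("^[%s]+$", paste(.AA20, collapse = "")),
                            out$peptide_sequence))
  if (length(bad_seq))
    stop(sprintf("row-level error in '%s', line %d: invalid peptide sequence '%s'",
                 path, bad_seq[1] + 1L, out$peptide_sequence[bad_seq[1]]))
  no_int <- which(is.na(out$intensity_heavy) & is.na(out$intensity_light))
  if (length(no_int))
    stop(sprintf("row-level error in '%s', line %d: both channel intensities absent",
                 path, no_int[1] + 1L))
  out
}

#' Read a protein-groups table
#'
#' Flag columns follow the "+"-marker dialect: a cell containing `+` means
#' flagged, an empty cell means not flagged. Semicolon-separated member
#' protein identifiers are split in order into a list column.
#'
#' @inheritParams read_evidence
#' @param columns column map, see [protein_group_columns()].
#' @return data.frame with columns `protein_group_id`, `member_protein_ids`
#'   (list of character vectors), `ratio_hl_normalized`, `intensity_heavy`,
#'   `intensity_light`, `flag_reverse`, `flag_contaminant`,
#'   `flag_only_by_site`.
#' @export
read_protein_groups <- function(path, columns = protein_group_columns()) {
  df <- .read_tsv_raw(path)
  .require_columns(df, columns, c("protein_group_id", "member_protein_ids"), path)
  members <- strsplit(.get_chr(df, columns, "member_protein_ids"), ";", fixed = TRUE)
  out <- data.frame(
    protein_group_id    = .get_chr(df, columns, "protein_group_id"),
    ratio_hl_normalized = .get_num(df, columns, "ratio_hl_normalized", path),
    intensity_heavy     = .get_num(df, columns, "intensity_heavy", path),
    intensity_light     = .get_num(df, columns, "intensity_light", path),
    flag_reverse        = .parse_flag(.get_chr(df, columns, "flag_reverse", "")),
    flag_contaminant    = .parse_flag(.get_chr(df, columns, "flag_contaminant", "")),
    flag_only_by_site   = .parse_flag(.get_chr(df, columns, "flag_only_by_site", "")),
    stringsAsFactors = FALSE
  )
  out$member_protein_ids <- members
  if (any(lengths(members) == 0 | !nzchar(vapply(members, `[`, "", 1))))
    stop(sprintf("format error in '%s': empty member protein ID list", path))
  out
}

#' Read a phosphosite table
#'
#' Per-replicate normalized heavy/light site ratios are read from all
#' columns whose header starts with `"Ratio H/L normalized "`; the suffix is
#' the replicate label (e.g. `b1t2` = biological replicate 1, technical
#' replicate 2). They become internal columns `ratio_hl.<label>`.
#'
#' @inheritParams read_evidence
#' @param columns column map, see [site_columns()].
#' @return data.frame with site fields plus one `ratio_hl.<label>` column
#'   per replicate; the labels are stored in `attr(, "ratio_labels")`.
#' @export
read_sites <- function(path, columns = site_columns()) {
  df <- .read_tsv_raw(path)
  .require_columns(df, columns,
                   c("protein_group_id", "position", "residue",
                     "localization_prob"), path)
  out <- data.frame(
    protein_group_id  = .get_chr(df, columns, "protein_group_id"),
    position          = as.integer(.get_num(df, columns, "position", path)),
    residue           = .get_chr(df, columns, "residue"),
    localization_prob = .get_num(df, columns, "localization_prob", path),
    intensity_heavy   = .get_num(df, columns, "intensity_heavy", path),
    intensity_light   = .get_num(df, columns, "intensity_light", path),
    stringsAsFactors = FALSE
  )
  bad_res <- which(!(out$residue %in% c("S", "T", "Y")))
  if (length(bad_res))
    stop(sprintf("row-level error in '%s', line %d: residue '%s' not one of S/T/Y",
                 path, bad_res[1] + 1L, out$residue[bad_res[1]]))
  bad_lp <- which(is.na(out$localization_prob) | out$localization_prob < 0 |
                    out$localization_prob > 1)
  if (length(bad_lp))
    stop(sprintf("row-level error in '%s', line %d: localization probability outside [0,1]",
                 path, bad_lp[1] + 1L))
  ratio_hdrs <- grep(paste0("^", .SITE_RATIO_PREFIX), names(df), value = TRUE)
  labels <- sub(.SITE_RATIO_PREFIX, "", ratio_hdrs, fixed = TRUE)
  for (i in seq_along(ratio_hdrs))
    out[[paste0("ratio_hl.", labels[i])]] <-
      .parse_numeric(df[[ratio_hdrs[i]]], ratio_hdrs[i], path)
  attr(out, "ratio_labels") <- labels
  out
}

#' Read / write GMT gene-set files
#'
#' The GMT format is one set per line: set id, description, then one or more
#' member identifiers, all tab-separated. A line with no members is a format
#' error.
#'
#' @param path path to a `.gmt` file.
#' @return `read_gmt()`: named list of gene sets, each a
#'   `list(set_id, description, members)`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("format error in '%s', line %d: GMT line has no members", path, i))
    list(set_id = f[1], description = f[2], members = unique(f[-(1:2)]))
  })
  ids <- vapply(sets, `[[`, "", "set_id")
  if (anyDuplicated(ids))
    stop(sprintf("format error in '%s': duplicated set id(s): %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  names(sets) <- ids
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene sets as returned by [read_gmt()].
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$set_id, s$description, s$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a functional-category annotation map
#'
#' Tab-separated map from protein identifier to functional category, with an
#' optional third "+"-marker column flagging mitochondrial proteins
#' (MitoXplorer-style annotation). Each protein maps to at most one
#' category.
#'
#' @param path path to a 2- or 3-column TSV with header
#'   `Protein ID`, `Category`[, `Mitochondrial`].
#' @return data.frame with columns `protein_id`, `functional_category`,
#'   `is_mitochondrial`.
#' @export
read_annotation <- function(path) {
  df <- .read_tsv_raw(path)
  need <- c("Protein ID", "Category")
  if (!all(need %in% names(df)))
    stop(sprintf("format error in '%s': missing mandatory column(s): %s", path,
                 paste(sprintf("'%s'", setdiff(need, names(df))), collapse = ", ")))
  out <- data.frame(
    protein_id          = trimws(df[["Protein ID"]]),
    functional_category = trimws(df[["Category"]]),
    is_mitochondrial    = if ("Mitochondrial" %in% names(df))
      .parse_flag(df[["Mitochondrial"]]) else rep(FALSE, nrow(df)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$protein_id))
    stop(sprintf("format error in '%s': protein(s) with more than one category: %s",
                 path, paste(unique(out$protein_id[duplicated(out$protein_id)]),
                             collapse = ", ")))
  out
}

#' @rdname read_annotation
#' @param annotation data.frame as returned by [read_annotation()].
#' @export
write_annotation <- function(annotation, path) {
  df <- data.frame(
    `Protein ID`    = annotation$protein_id,
    Category        = annotation$functional_category,
    Mitochondrial   = ifelse(isTRUE_vec(annotation$is_mitochondrial), "+", ""),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  .write_tsv(df, path)
}

isTRUE_vec <- function(x) !is.na(x) & x

.write_tsv <- function(df, path) {
  # list columns (member IDs) are collapsed with ";"
  is_list <- vapply(df, is.list, TRUE)
  for (j in which(is_list))
    df[[j]] <- vapply(df[[j]], paste, "", collapse = ";")
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    TRUE
  }, error = function(e)
    stop(sprintf("I/O failure writing '%s': %s", path, conditionMessage(e))))
  invisible(path)
}

#' Write pipeline tables
#'
#' `write_results_tsv()` writes any result data.frame as TSV with a stable
#' column order (the data.frame's own order); missing values become empty
#' cells. The dedicated writers emit the exact dialect the corresponding
#' readers consume, so write-then-read round-trips are lossless.
#'
#' @param records data.frame to write.
#' @param path output file path.
#' @export
write_results_tsv <- function(records, path) .write_tsv(records, path)

#' @rdname write_results_tsv
#' @param evidence evidence data.frame in internal representation.
#' @param columns column map used to name the headers.
#' @export
write_evidence <- function(evidence, path, columns = evidence_columns()) {
  df <- evidence[, names(columns)[names(columns) %in% names(evidence)], drop = FALSE]
  names(df) <- columns[names(df)]
  .write_tsv(df, path)
}

#' @rdname write_results_tsv
#' @param protein_groups protein-groups data.frame in internal representation.
#' @export
write_protein_groups <- function(protein_groups, path,
                                 columns = protein_group_columns()) {
  df <- protein_groups
  for (f in c("flag_reverse", "flag_contaminant", "flag_only_by_site"))
    df[[f]] <- ifelse(isTRUE_vec(df[[f]]), "+", "")
  df <- df[, names(columns)[names(columns) %in% names(df)], drop = FALSE]
  names(df) <- columns[names(df)]
  .write_tsv(df, path)
}

#' @rdname write_results_tsv
#' @param sites site data.frame in internal representation.
#' @export
write_sites <- function(sites, path, columns = site_columns()) {
  fixed <- names(columns)[names(columns) %in% names(sites)]
  ratio_cols <- grep("^ratio_hl\\.", names(sites), value = TRUE)
  df <- sites[, c(fixed, ratio_cols), drop = FALSE]
  names(df) <- c(columns[fixed],
                 paste0(.SITE_RATIO_PREFIX, sub("^ratio_hl\\.", "", ratio_cols)))
  .write_tsv(df, path)
}
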