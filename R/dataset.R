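#' Default column map for compactness CSV files
#'
#' Maps the columns of a specimen table on disk to the fields used by the
#' package. The source files in this literature circulate with slightly
#' different headers, so readers take an explicit map rather than guessing.
#'
#' @param taxon,diameter,compactness,flying,diving Column names in the file.
#' @param status,role Optional column names for extinct/extant status and
#'   train/test role; `NULL` means the column is absent and the field is
#'   filled with `"unknown"` / `"train"`.
#'
#' @return A named list understood by [read_compactness_csv()].
#' @export
compactness_columns <- function(taxon = "taxon", diameter = "diameter",
                                compactness = "compactness", flying = "flying",
                                diving = "diving", status = NULL, role = NULL) {
  list(taxon = taxon, diameter = diameter, compactness = compactness,
       flying = flying, diving = diving, status = status, role = role)
}

code_levels <- c("0", "1", "2", "unknown")

normalize_code <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | x == "" | !(x %in% c("0", "1", "2"))] <- "unknown"
  x
}

#' Validate a specimen table
#'
#' Checks the record-level invariants: positive bone diameter, compactness in
#' (0, 1], unique taxon identifiers, and valid categorical codes. Violations
#' raise an error naming the offending rows.
#'
#' @param ds A tibble as returned by [read_compactness_csv()].
#' @return `ds`, invisibly, if valid.
#' @export
validate_compactness <- function(ds) {
  required <- c("taxon_id", "md_mm", "cg", "fly_code", "dive_code", "status", "role")
  missing <- setdiff(required, names(ds))
  if (length(missing) > 0) {
    abort(paste0("specimen table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(ds) == 0) abort("specimen table has no records")
  bad_cg <- which(!is.finite(ds$cg) | ds$cg <= 0 | ds$cg > 1)
  if (length(bad_cg) > 0) {
    abort(paste0("Cg must lie in (0, 1]; violated at row(s) ",
                 paste(head(bad_cg, 5), collapse = ", "),
                 " (taxon ", ds$taxon_id[bad_cg[1]], ", Cg = ",
                 ds$cg[bad_cg[1]], ")"))
  }
  bad_md <- which(!is.finite(ds$md_mm) | ds$md_mm <= 0)
  if (length(bad_md) > 0) {
    abort(paste0("bone diameter must be positive; violated at row(s) ",
                 paste(head(bad_md, 5), collapse = ", ")))
  }
  if (anyDuplicated(ds$taxon_id)) {
    abort(paste0("duplicate taxon_id: ",
                 ds$taxon_id[anyDuplicated(ds$taxon_id)]))
  }
  invisible(ds)
}

#' Read a specimen compactness table
#'
#' Reads a comma-separated specimen table (one row per specimen: taxon name,
#' maximum bone diameter, global bone compactness Cg, flying and diving
#' lifestyle codes) into the package's canonical tibble layout. Diameter is
#' always stored linear in millimetres; files holding `log10(MD)` are
#' converted on read. Duplicate taxon names (multiple specimens of one taxon)
#' are kept as distinct records with a disambiguating numeric suffix.
#'
#' @param path Path to a CSV file with a header row.
#' @param column_map A map from [compactness_columns()].
#' @param md_scale `"linear"` (millimetres), `"log10"`, or `"auto"`
#'   (treat as log10 when every diameter is below 3, a value no real bone
#'   table in millimetres attains for its maximum).
#' @param name Dataset label stored as an attribute.
#'
#' @return A tibble with columns `taxon_id`, `md_mm`, `cg`, `fly_code`,
#'   `dive_code`, `status`, `role`.
#' @export
read_compactness_csv <- function(path, column_map = compactness_columns(),
                                 md_scale = c("linear", "log10", "auto"),
                                 name = basename(path)) {
  md_scale <- match.arg(md_scale)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- unlist(column_map[c("taxon", "diameter", "compactness", "flying", "diving")])
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(paste0("mapped column(s) absent from ", basename(path), ": ",
                 paste(missing, collapse = ", ")))
  }
  md <- suppressWarnings(as.numeric(raw[[column_map$diameter]]))
  cg <- suppressWarnings(as.numeric(raw[[column_map$compactness]]))
  if (anyNA(md) || anyNA(cg)) {
    abort(paste0("non-numeric diameter or compactness at row(s) ",
                 paste(head(which(is.na(md) | is.na(cg)), 5), collapse = ", ")))
  }
  if (md_scale == "auto") {
    md_scale <- if (max(md, na.rm = TRUE) < 3) "log10" else "linear"
  }
  if (md_scale == "log10") md <- 10^md
  status <- if (!is.null(column_map$status) && column_map$status %in% names(raw)) {
    s <- trimws(as.character(raw[[column_map$status]]))
    s[!(s %in% c("extinct", "extant"))] <- "unknown"
    s
  } else rep("unknown", nrow(raw))
  role <- if (!is.null(column_map$role) && column_map$role %in% names(raw)) {
    r <- trimws(as.character(raw[[column_map$role]]))
    r[!(r %in% c("train", "test"))] <- "train"
    r
  } else rep("train", nrow(raw))
  ds <- tibble::tibble(
    taxon_id = make.unique(trimws(as.character(raw[[column_map$taxon]])), sep = "_"),
    md_mm = md,
    cg = cg,
    fly_code = normalize_code(raw[[column_map$flying]]),
    dive_code = normalize_code(raw[[column_map$diving]]),
    status = status,
    role = role
  )
  validate_compactness(ds)
  attr(ds, "dataset_name") <- name
  ds
}

#' Write a specimen compactness table
#'
#' Inverse of [read_compactness_csv()] under the default column map: the
#' written file reads back field-for-field.
#'
#' @param ds Specimen tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compactness_csv <- function(ds, path) {
  validate_compactness(ds)
  out <- tibble::tibble(
    taxon = ds$taxon_id, diameter = ds$md_mm, compactness = ds$cg,
    flying = ds$fly_code, diving = ds$dive_code,
    status = ds$status, role = ds$role
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Split a specimen table into the two discriminant classes
#'
#' Assigns each training record to class 1 (non-diver reference) or class 2
#' (nonflying frequent diver, `F0D2`) according to the comparison rule.
#' `"F0D0_vs_F0D2"` restricts class 1 to fully terrestrial taxa (`F0D0`) and
#' drops everything else; `"Many_vs_F0D2"` keeps every coded taxon that is not
#' `F0D2` in class 1. Records with unknown codes, and records flagged
#' `role = "test"`, never enter either class.
#'
#' @param ds Specimen tibble.
#' @param rule `"F0D0_vs_F0D2"` or `"Many_vs_F0D2"`.
#' @param min_per_class Minimum records per class for a discriminant fit.
#'
#' @return The subset of `ds` with an added integer `class` column (1 or 2)
#'   and the rule stored in the `"class_rule"` attribute.
#' @export
partition_classes <- function(ds, rule = c("F0D0_vs_F0D2", "Many_vs_F0D2"),
                              min_per_class = 3L) {
  rule <- match.arg(rule)
  validate_compactness(ds)
  d <- dplyr::filter(ds, .data$role == "train",
                     .data$fly_code != "unknown", .data$dive_code != "unknown")
  is_diver <- d$fly_code == "0" & d$dive_code == "2"
  if (rule == "F0D0_vs_F0D2") {
    keep <- is_diver | (d$fly_code == "0" & d$dive_code == "0")
    d <- d[keep, , drop = FALSE]
    is_diver <- is_diver[keep]
  }
  d$class <- ifelse(is_diver, 2L, 1L)
  n1 <- sum(d$class == 1L); n2 <- sum(d$class == 2L)
  if (n1 < min_per_class || n2 < min_per_class) {
    abort(paste0("partition under rule ", rule, " leaves a class with fewer than ",
                 min_per_class, " records (class 1: ", n1, ", class 2: ", n2, ")"))
  }
  attr(d, "class_rule") <- rule
  d
}

#' Taxa shared between two specimen tables
#'
#' Exact-string intersection of taxon identifiers, after optional whitespace
#' normalization (trim plus internal-whitespace collapse).
#'
#' @param a,b Specimen tibbles.
#' @param normalize Normalize whitespace before matching.
#' @return Character vector of shared names; its length is the shared count.
#' @export
shared_taxa <- function(a, b, normalize = TRUE) {
  norm <- function(x) if (normalize) gsub("\\s+", " ", trimws(x)) else x
  sort(intersect(norm(a$taxon_id), norm(b$taxon_id)))
}

#' Analysis coordinates of a specimen table
#'
#' The discriminant works in the plane (log10 diameter, compactness). This
#' helper adds the analysis coordinates `x = log10(md_mm)` and `y = cg`.
#'
#' @param ds Specimen tibble (optionally with a `class` column).
#' @return `ds` with `x` and `y` columns appended.
#' @export
as_points <- function(ds) {
  dplyr::mutate(ds, x = log10(.data$md_mm), y = .data$cg)
}
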