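#' Read a homotopic pair map
#'
#' The pair map is the package's only description of the parcellation: one row
#' per homotopic pair, giving a pair id, the labels of the left- and
#' right-hemisphere member regions, and the cortical hierarchy zone the pair
#' belongs to (Mesulam's scheme: primary, unimodal, heteromodal, paralimbic,
#' limbic, subcortical). Region columns in time-series matrices are always
#' matched by label through this map, never by position.
#'
#' @param path Path to a tab-separated file with header columns
#'   `pair_id`, `left`, `right`, `zone`. Lines starting with `#` are ignored.
#' @return A `homotopic_atlas` object: a list with elements `pairs`
#'   (data.frame of pair_id, left, right, zone), `region_index` (named integer
#'   vector mapping region label to its canonical column index, in declaration
#'   order: left then right within each row), and `hemisphere` (named character
#'   vector, "L" or "R" per region).
#' @seealso [homotopic_atlas()] to build the same object from a data.frame.
#' @export
read_pair_map <- function(path) {
  tab <- read_tsv_table(path)
  homotopic_atlas(tab)
}

#' Construct and validate a homotopic atlas
#'
#' @param pairs data.frame with columns `pair_id`, `left`, `right`, `zone`.
#' @return A validated `homotopic_atlas` object.
#' @export
homotopic_atlas <- function(pairs) {
  need <- c("pair_id", "left", "right", "zone")
  miss <- setdiff(need, names(pairs))
  if (length(miss) > 0)
    stop("pair map is missing column(s): ", paste(miss, collapse = ", "))
  pairs <- as.data.frame(pairs)[, need]
  for (cl in need) pairs[[cl]] <- as.character(pairs[[cl]])

  if (anyDuplicated(pairs$pair_id))
    stop("duplicate pair_id: ",
         paste(unique(pairs$pair_id[duplicated(pairs$pair_id)]), collapse = ", "))
  same <- pairs$left == pairs$right
  if (any(same))
    stop("left and right labels identical in pair(s): ",
         paste(pairs$pair_id[same], collapse = ", "))
  regions <- as.vector(rbind(pairs$left, pairs$right))
  dup <- unique(regions[duplicated(regions)])
  if (length(dup) > 0)
    stop("duplicate region label: ", paste(dup, collapse = ", "))
  bad_zone <- setdiff(unique(pairs$zone), hierarchy_zones())
  if (length(bad_zone) > 0)
    stop("unknown zone: ", paste(bad_zone, collapse = ", "),
         " (expected one of ", paste(hierarchy_zones(), collapse = ", "), ")")

  region_index <- stats::setNames(seq_along(regions), regions)
  hemisphere <- stats::setNames(rep(c("L", "R"), nrow(pairs)), regions)
  structure(list(pairs = pairs, region_index = region_index,
                 hemisphere = hemisphere),
            class = "homotopic_atlas")
}

#' The six cortical hierarchy zones
#'
#' @return Character vector of the admissible `zone` values, from primary
#'   sensory/motor cortex to subcortical structures.
#' @export
hierarchy_zones <- function() {
  c("primary", "unimodal", "heteromodal", "paralimbic", "limbic", "subcortical")
}

#' @export
print.homotopic_atlas <- function(x, ...) {
  cat("homotopic_atlas:", nrow(x$pairs), "pairs,",
      length(x$region_index), "regions\n")
  cat("zones:", paste(names(table(x$pairs$zone)), table(x$pairs$zone),
                      sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of pairs / regions in an atlas
#' @param atlas A `homotopic_atlas`.
#' @return Integer count.
#' @export
n_pairs <- function(atlas) nrow(atlas$pairs)

#' @rdname n_pairs
#' @export
n_regions <- function(atlas) length(atlas$region_index)

#' Read a delimited numeric matrix
#'
#' Reads a tab-separated numeric matrix (frames x regions for time series).
#' A first line of non-numeric fields is taken as column labels. Ragged rows
#' and non-numeric cells are reported with their row number.
#'
#' @param path File path; lines starting with `#` are skipped.
#' @return Numeric matrix, with column names when the file has a header.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) stop("empty matrix file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol1 <- length(fields[[1]])
  widths <- lengths(fields)
  if (any(widths != ncol1))
    stop("ragged row ", which(widths != ncol1)[1], " in ", path,
         " (expected ", ncol1, " fields, got ", widths[widths != ncol1][1], ")")
  first <- suppressWarnings(as.numeric(fields[[1]]))
  has_header <- anyNA(first)
  header <- if (has_header) fields[[1]] else NULL
  body <- if (has_header) fields[-1] else fields
  if (length(body) == 0) stop("matrix file has a header but no data: ", path)
  vals <- suppressWarnings(as.numeric(unlist(body, use.names = FALSE)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    row <- (bad - 1) %/% ncol1 + 1 + has_header
    col <- (bad - 1) %% ncol1 + 1
    stop("non-numeric cell at row ", row, ", column ", col, " in ", path)
  }
  m <- matrix(vals, ncol = ncol1, byrow = TRUE)
  if (has_header) colnames(m) <- header
  m
}

#' Write a numeric matrix as TSV
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @param meta Optional named list written as leading `#key=value` lines.
#' @export
write_matrix <- function(m, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, meta)
  if (!is.null(colnames(m)))
    writeLines(paste(colnames(m), collapse = "\t"), con)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a pedigree table
#'
#' Columns: `id`, `father`, `mother`, `mz_group`; empty fields mean unknown
#' parent / not an MZ twin. Validates acyclicity (no individual is its own
#' ancestor) and that both members of an MZ group share both parents.
#'
#' @param path TSV path.
#' @return data.frame of class `pedigree` with character columns and `NA` for
#'   missing parents.
#' @export
read_pedigree <- function(path) {
  tab <- read_tsv_table(path)
  validate_pedigree(tab)
}

#' @rdname read_pedigree
#' @param ped data.frame with the pedigree columns.
#' @export
validate_pedigree <- function(ped) {
  need <- c("id", "father", "mother", "mz_group")
  miss <- setdiff(need, names(ped))
  if (length(miss) > 0)
    stop("pedigree is missing column(s): ", paste(miss, collapse = ", "))
  ped <- as.data.frame(ped)[, need]
  for (cl in need) {
    ped[[cl]] <- as.character(ped[[cl]])
    ped[[cl]][!is.na(ped[[cl]]) & ped[[cl]] == ""] <- NA_character_
  }
  if (anyDuplicated(ped$id))
    stop("duplicate individual id: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  for (pc in c("father", "mother")) {
    known <- ped[[pc]][!is.na(ped[[pc]])]
    unk <- setdiff(known, ped$id)
    if (length(unk) > 0)
      stop(pc, " id(s) not present as individuals: ",
           paste(unk, collapse = ", "))
  }
  # topological check: repeatedly peel individuals whose parents are resolved
  resolved <- character(0)
  remaining <- ped$id
  repeat {
    idx <- match(remaining, ped$id)
    ok <- (is.na(ped$father[idx]) | ped$father[idx] %in% resolved) &
      (is.na(ped$mother[idx]) | ped$mother[idx] %in% resolved)
    if (!any(ok)) break
    resolved <- c(resolved, remaining[ok])
    remaining <- remaining[!ok]
    if (length(remaining) == 0) break
  }
  if (length(remaining) > 0)
    stop("pedigree contains a parentage cycle involving: ",
         paste(remaining, collapse = ", "))
  mz <- ped$mz_group[!is.na(ped$mz_group)]
  for (g in unique(mz)) {
    members <- ped[!is.na(ped$mz_group) & ped$mz_group == g, ]
    if (nrow(members) != 2)
      stop("MZ group ", g, " must have exactly 2 members, has ", nrow(members))
    if (!identical(members$father[1], members$father[2]) ||
        !identical(members$mother[1], members$mother[2]))
      stop("MZ group ", g, " members do not share both parents")
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Read a per-subject covariate table
#'
#' Columns `subject_id`, `age` (years), `sex` (0/1), `handedness`
#' (-100..100). Rows with missing values in these columns are rejected.
#'
#' @param path TSV path.
#' @return data.frame with one row per subject.
#' @export
read_covariates <- function(path) {
  tab <- read_tsv_table(path)
  need <- c("subject_id", "age", "sex", "handedness")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("covariate table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject_id in covariate table")
  for (cl in c("age", "sex", "handedness")) {
    tab[[cl]] <- as.numeric(tab[[cl]])
    if (anyNA(tab[[cl]]))
      stop("missing or non-numeric values in covariate column ", cl)
  }
  if (!all(tab$sex %in% c(0, 1))) stop("sex must be coded 0/1")
  tab
}

#' Expand covariates into a model design
#'
#' Builds the derived interaction columns used by the heritability and GLM
#' models: age^2, age x sex, age^2 x sex.
#'
#' @param covariates Covariate data.frame with `age` and `sex` columns.
#' @param terms Character vector of columns/derived terms to include.
#' @return Numeric matrix (subjects x terms), no intercept column.
#' @export
covariate_design <- function(covariates,
                             terms = c("age", "sex", "age2", "age_sex",
                                       "age2_sex", "handedness")) {
  age <- covariates$age
  sex <- covariates$sex
  pool <- list(age = age, sex = sex, age2 = age^2, age_sex = age * sex,
               age2_sex = age^2 * sex, handedness = covariates$handedness)
  extra <- setdiff(terms, names(pool))
  for (e in extra) pool[[e]] <- as.numeric(covariates[[e]])
  out <- do.call(cbind, pool[terms])
  colnames(out) <- terms
  out
}

#' Read a task event table
#'
#' Columns `onset` (s), `duration` (s), `condition`. The condition name
#' `"fixation"` is reserved for fixation blocks (no task regressor is built
#' for it; its frames are discarded in background-connectivity estimation).
#'
#' @param path TSV path.
#' @return data.frame of events ordered by onset.
#' @export
read_events <- function(path) {
  tab <- read_tsv_table(path)
  validate_events(tab)
}

#' @rdname read_events
#' @param events data.frame with onset, duration, condition.
#' @export
validate_events <- function(events) {
  need <- c("onset", "duration", "condition")
  miss <- setdiff(need, names(events))
  if (length(miss) > 0)
    stop("event table is missing column(s): ", paste(miss, collapse = ", "))
  events <- as.data.frame(events)
  events$onset <- as.numeric(events$onset)
  events$duration <- as.numeric(events$duration)
  events$condition <- as.character(events$condition)
  if (anyNA(events$onset) || anyNA(events$duration))
    stop("non-numeric onset/duration in event table")
  if (any(events$onset < 0)) stop("negative event onset")
  if (any(events$duration < 0)) stop("negative event duration")
  events[order(events$onset), , drop = FALSE]
}

#' Reserved fixation condition name
#' @return The string `"fixation"`.
#' @export
fixation_condition <- function() "fixation"

#' Write a result table as TSV with metadata header
#'
#' All result tables are written in one canonical dialect: optional
#' `#key=value` metadata lines, a header line, tab-separated fields,
#' full double precision for numerics.
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param meta Named list of metadata values (e.g. seed, config hash).
#' @export
write_result_table <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, meta)
  df2 <- df
  for (j in seq_along(df2))
    if (is.numeric(df2[[j]]))
      df2[[j]] <- format(df2[[j]], digits = 17, trim = TRUE,
                         scientific = FALSE)
  utils::write.table(df2, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table written by this package
#'
#' @param path Path; `#`-prefixed metadata lines are skipped.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_meta <- function(con, meta) {
  if (is.null(meta)) return(invisible(NULL))
  for (k in names(meta))
    writeLines(paste0("#", k, "=", as.character(meta[[k]])), con)
  invisible(NULL)
}
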