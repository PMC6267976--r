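#' Species trait table
#'
#' Construct and validate a table of species-level functional traits. The
#' pipeline works with three traits measured on three different organs:
#' seed mass (mg, oven-dry mass of an average seed), specific root length
#' (SRL, m g^-1, fine-root length per unit dry mass) and mean Julian
#' flowering date (day of year). These are the \eqn{t_i} vectors that enter
#' community-weighted means and the CATS constraints.
#'
#' @param df data frame with columns `species_id`, `seed_mass`, `srl`,
#'   `flowering_date`.
#' @return A `trait_table`: a data frame with one row per species, validated
#'   so that species ids are unique, seed mass and SRL are strictly positive
#'   and flowering dates lie in day-of-year range.
#' @examples
#' trait_table(data.frame(
#'   species_id = c("BOGR", "POFE"),
#'   seed_mass = c(0.3, 0.35), srl = c(210, 85),
#'   flowering_date = c(212, 152)
#' ))
#' @export
trait_table <- function(df) {
  required <- c("species_id", "seed_mass", "srl", "flowering_date")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("trait table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[required]
  df$species_id <- as.character(df$species_id)
  if (anyDuplicated(df$species_id)) {
    dup <- unique(df$species_id[duplicated(df$species_id)])
    stop("duplicate species_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  for (col in c("seed_mass", "srl", "flowering_date")) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      stop("trait '", col, "' must be finite numeric with no missing values",
           call. = FALSE)
    }
  }
  bad_mass <- df$species_id[df$seed_mass <= 0]
  if (length(bad_mass) > 0) {
    stop("seed_mass must be > 0; offending species: ",
         paste(bad_mass, collapse = ", "), call. = FALSE)
  }
  bad_srl <- df$species_id[df$srl <= 0]
  if (length(bad_srl) > 0) {
    stop("srl must be > 0; offending species: ",
         paste(bad_srl, collapse = ", "), call. = FALSE)
  }
  bad_fd <- df$species_id[df$flowering_date < 1 | df$flowering_date > 366]
  if (length(bad_fd) > 0) {
    stop("flowering_date must lie in [1, 366]; offending species: ",
         paste(bad_fd, collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Names of the trait columns in a trait table
#' @param traits a `trait_table`
#' @return character vector of trait column names.
#' @export
trait_names <- function(traits) {
  setdiff(names(traits), "species_id")
}

#' Trait table as a species x trait numeric matrix
#' @param traits a `trait_table`
#' @return numeric matrix with species ids as row names.
#' @export
trait_matrix <- function(traits) {
  m <- as.matrix(as.data.frame(traits)[trait_names(traits)])
  rownames(m) <- traits$species_id
  m
}

#' Read a species trait table from CSV
#'
#' One species per row; columns `species_id`, `seed_mass`, `srl`,
#' `flowering_date`. Row order is preserved.
#'
#' @param path path to a CSV file with a header row.
#' @return a validated [trait_table()].
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  trait_table(df)
}

#' Write a trait table to CSV
#' @param traits a `trait_table`
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  utils::write.csv(as.data.frame(traits), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sample x species community matrix
#'
#' A nonnegative abundance matrix: percent foliar cover for field quadrats,
#' seedling counts for experimental pots, or relative abundances (rows on the
#' unit simplex). Rows are samples, columns species. Rows that are entirely
#' zero are legal but flagged, mirroring sown pots in which no
#' germination-emergence occurred; downstream fitting excludes them.
#'
#' @param x numeric matrix (or object coercible to one) with sample ids as
#'   row names and species ids as column names.
#' @param kind one of `"cover"`, `"count"`, `"relative"`.
#' @param treatment optional per-sample treatment labels (length `nrow(x)`).
#' @return a `community_matrix`: the numeric matrix with attributes `kind`,
#'   `zero_rows` (logical flag per sample) and optionally `treatment`.
#' @export
community_matrix <- function(x, kind = c("cover", "count", "relative"),
                             treatment = NULL) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x))) rownames(x) <- paste0("sample", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("sp", seq_len(ncol(x)))
  if (anyNA(x) || any(!is.finite(x))) {
    stop("community matrix must be finite with no missing values", call. = FALSE)
  }
  if (any(x < 0)) {
    stop("community matrix values must be nonnegative", call. = FALSE)
  }
  rs <- rowSums(x)
  zero_rows <- rs == 0
  if (kind == "relative") {
    bad <- !zero_rows & abs(rs - 1) > 1e-9
    if (any(bad)) {
      stop("relative-abundance rows must sum to 1 (tolerance 1e-9); offending rows: ",
           paste(utils::head(rownames(x)[bad], 5), collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(treatment)) {
    if (length(treatment) != nrow(x)) {
      stop("treatment labels must have one entry per sample", call. = FALSE)
    }
    attr(x, "treatment") <- as.character(treatment)
  }
  attr(x, "kind") <- kind
  attr(x, "zero_rows") <- stats::setNames(zero_rows, rownames(x))
  class(x) <- c("community_matrix", class(x))
  x
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("community matrix (", attr(x, "kind"), "): ",
      nrow(x), " samples x ", ncol(x), " species\n", sep = "")
  nz <- sum(attr(x, "zero_rows"))
  if (nz > 0) cat("  ", nz, " all-zero (flagged) sample(s)\n", sep = "")
  if (!is.null(attr(x, "treatment"))) {
    cat("  treatments: ",
        paste(names(table(attr(x, "treatment"))), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read a community matrix from CSV
#'
#' Wide format: one sample per row, first column `sample_id`, remaining
#' columns one species each. An optional `treatment` column (any position
#' after `sample_id`) carries per-sample treatment labels.
#'
#' @param path path to a CSV file with header row.
#' @param kind abundance type stored in the file: `"cover"`, `"count"` or
#'   `"relative"`.
#' @return a [community_matrix()].
#' @export
read_community_matrix <- function(path, kind = c("cover", "count", "relative")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("community matrix CSV must have a 'sample_id' column", call. = FALSE)
  }
  treatment <- NULL
  if ("treatment" %in% names(df)) {
    treatment <- as.character(df$treatment)
    df$treatment <- NULL
  }
  ids <- as.character(df$sample_id)
  df$sample_id <- NULL
  m <- as.matrix(df)
  rownames(m) <- ids
  community_matrix(m, kind = kind, treatment = treatment)
}

#' Write a community matrix to CSV
#' @param m a `community_matrix`
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_community_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), check.names = FALSE)
  if (!is.null(attr(m, "treatment"))) df$treatment <- attr(m, "treatment")
  df <- cbind(df, as.data.frame(unclass_matrix(m), check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# strip community_matrix attributes, keep dimnames
unclass_matrix <- function(m) {
  out <- as.matrix(m)
  attr(out, "kind") <- NULL
  attr(out, "zero_rows") <- NULL
  attr(out, "treatment") <- NULL
  class(out) <- "matrix"
  dim(out) <- dim(m)
  dimnames(out) <- dimnames(m)
  out
}

#' Sample x environment table
#'
#' Per-sample environmental measurements: soil pH and ponderosa pine basal
#' area (m^2 ha^-1, cross-sectional stem area per hectare, a proxy for
#' canopy shading and belowground competition).
#'
#' @param df data frame with columns `sample_id`, `soil_ph`, `pine_ba`.
#' @return an `environment_table` data frame.
#' @export
environment_table <- function(df) {
  required <- c("sample_id", "soil_ph", "pine_ba")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("environment table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[required]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in environment table", call. = FALSE)
  }
  if (anyNA(df$soil_ph) || any(!is.finite(df$soil_ph)) ||
      anyNA(df$pine_ba) || any(!is.finite(df$pine_ba))) {
    stop("environmental values must be finite", call. = FALSE)
  }
  if (any(df$pine_ba < 0)) stop("pine_ba must be >= 0", call. = FALSE)
  if (any(df$soil_ph < 3 | df$soil_ph > 10)) {
    stop("soil_ph outside plausible range [3, 10]", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("environment_table", "data.frame")
  df
}

#' Read an environment table from CSV
#' @param path path to a CSV file with columns `sample_id`, `soil_ph`, `pine_ba`.
#' @return an [environment_table()].
#' @export
read_environment_table <- function(path) {
  environment_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write an environment table to CSV
#' @param env an `environment_table`
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_environment_table <- function(env, path) {
  utils::write.csv(as.data.frame(env), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Relativize a community matrix
#'
#' Convert cover or count data to relative abundances by dividing each row
#' by its row total (each species' percent of the sample's total cover).
#' All-zero rows are left as zeros and stay flagged via the `zero_rows`
#' attribute; they produce missing CWMs downstream and are excluded from
#' model fitting.
#'
#' @param m a `community_matrix` of kind `"cover"` or `"count"`. Relative
#'   input is returned unchanged (the operation is idempotent).
#' @return a `community_matrix` of kind `"relative"`.
#' @examples
#' m <- community_matrix(rbind(c(30, 10, 10)), kind = "cover")
#' relativize(m)[1, ]
#' @export
relativize <- function(m) {
  if (!inherits(m, "community_matrix")) {
    stop("relativize() expects a community_matrix", call. = FALSE)
  }
  if (attr(m, "kind") == "relative") return(m)
  vals <- unclass_matrix(m)
  rs <- rowSums(vals)
  pos <- rs > 0
  vals[pos, ] <- vals[pos, , drop = FALSE] / rs[pos]
  community_matrix(vals, kind = "relative", treatment = attr(m, "treatment"))
}

#' Community-weighted mean traits
#'
#' For each sample, the abundance-weighted mean of each trait:
#' \deqn{\bar{T} = \sum_{i=1}^{S} p_i t_i}
#' where \eqn{p_i} is species \eqn{i}'s relative abundance in the sample and
#' \eqn{t_i} its trait value. Because each CWM is a convex combination of the
#' trait values of the species present, it always lies between the minimum
#' and maximum trait value among those species.
#'
#' @param rel a `community_matrix` of kind `"relative"` (use [relativize()]
#'   first for cover/count data).
#' @param traits a `trait_table` covering every species that has positive
#'   abundance in `rel`.
#' @return a `cwm_table`: data frame with `unit_id` and one column per
#'   trait. All-zero samples get `NA` CWMs.
#' @examples
#' tr <- trait_table(data.frame(species_id = c("a", "b"), seed_mass = c(2, 4),
#'                              srl = c(100, 200), flowering_date = c(150, 210)))
#' m <- relativize(community_matrix(
#'   matrix(c(1, 1), 1, dimnames = list("q1", c("a", "b"))), kind = "cover"))
#' compute_cwm(m, tr)
#' @export
compute_cwm <- function(rel, traits) {
  if (!inherits(rel, "community_matrix") || attr(rel, "kind") != "relative") {
    stop("compute_cwm() expects a relative-abundance community_matrix", call. = FALSE)
  }
  if (!inherits(traits, "trait_table")) traits <- trait_table(traits)
  present <- colnames(rel)[colSums(unclass_matrix(rel)) > 0]
  unknown <- setdiff(present, traits$species_id)
  if (length(unknown) > 0) {
    stop("species missing from trait table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tm <- trait_matrix(traits)
  common <- intersect(colnames(rel), rownames(tm))
  p <- unclass_matrix(rel)[, common, drop = FALSE]
  cwm <- p %*% tm[common, , drop = FALSE]
  cwm[attr(rel, "zero_rows"), ] <- NA_real_
  out <- data.frame(unit_id = rownames(rel), cwm, row.names = NULL,
                    check.names = FALSE)
  class(out) <- c("cwm_table", "data.frame")
  out
}

#' Read a CWM table from CSV
#' @param path CSV with a `unit_id` column and one column per trait.
#' @return a `cwm_table` data frame.
#' @export
read_cwm_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"unit_id" %in% names(df)) {
    stop("CWM table CSV must have a 'unit_id' column", call. = FALSE)
  }
  df$unit_id <- as.character(df$unit_id)
  class(df) <- c("cwm_table", "data.frame")
  df
}

#' Write a CWM table to CSV
#' @param cwm a `cwm_table`
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_cwm_table <- function(cwm, path) {
  utils::write.csv(as.data.frame(cwm), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
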