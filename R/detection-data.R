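#' Multi-season detection-history container
#'
#' Bundles per-year detection matrices with optional site covariates into the
#' object the fitting functions consume. Rows are sites (or, for the species
#' richness model, species), columns are within-year sampling periods; cells
#' are 1 (detected), 0 (sampled without detection) or \code{NA} (not
#' sampled).
#'
#' @param y List with one sites-x-periods matrix per year, all with the same
#'   rows in the same order. Year matrices may differ in column count.
#' @param site_covs Optional data frame of per-site covariates, one row per
#'   site in matching order.
#' @param species_id Optional species label carried through to outputs.
#' @param years Optional vector of year labels (defaults to names of \code{y}
#'   or \code{1:n_years}).
#' @return An object of class \code{occu_data}.
#' @export
occu_data <- function(y, site_covs = NULL, species_id = NULL, years = NULL) {
  if (is.matrix(y)) y <- list(y)
  if (!is.list(y) || !length(y)) stop("`y` must be a non-empty list of matrices")
  y <- lapply(y, function(m) {
    m <- as.matrix(m)
    vals <- m[!is.na(m)]
    if (length(vals) && !all(vals %in% c(0, 1)))
      stop("detection matrices may contain only 0, 1 and NA")
    storage.mode(m) <- "integer"
    m
  })
  n <- nrow(y[[1L]])
  if (any(vapply(y, nrow, 0L) != n))
    stop("all year matrices must have the same number of rows")
  if (is.null(years)) {
    years <- names(y)
    if (is.null(years)) years <- as.character(seq_along(y))
  }
  if (!is.null(site_covs)) {
    site_covs <- as.data.frame(site_covs)
    if (nrow(site_covs) != n)
      stop("`site_covs` must have one row per site")
  }
  structure(list(y = y, site_covs = site_covs, species_id = species_id,
                 years = years),
            class = "occu_data")
}

#' @export
print.occu_data <- function(x, ...) {
  st <- .detection_stats(x$y)
  cat(sprintf("Multi-season detection data%s\n",
              if (!is.null(x$species_id)) paste0(" for ", x$species_id) else ""))
  cat(sprintf("  %d sites, %d years, %s periods/year\n", nrow(st$d), ncol(st$d),
              paste(vapply(x$y, ncol, 0L), collapse = "/")))
  cat(sprintf("  detections per year: %s\n", paste(colSums(st$d), collapse = ", ")))
  cat(sprintf("  sampled cells per year: %s\n", paste(colSums(st$K), collapse = ", ")))
  invisible(x)
}

#' Build a daily detection matrix from events and deployments
#'
#' Turns raw detection events (one record per photographed species, site and
#' day) and camera deployment intervals into the sites-x-days ternary matrix
#' for one species and one year: 1 if the species was photographed at an
#' active site that day, 0 if the site was active without a detection, and
#' \code{NA} if the camera was not sampling. Duplicate events on the same
#' site-day collapse to a single detection.
#'
#' @param events Data frame with columns \code{species_id}, \code{site_id},
#'   \code{date} (\code{Date} or ISO-8601 string).
#' @param deployments Data frame with columns \code{site_id},
#'   \code{start_date}, \code{end_date}; intervals inclusive on both ends.
#' @param species_id Species to extract.
#' @param year Calendar year; the matrix columns span the earliest to latest
#'   active day among that year's deployments.
#' @return Integer matrix (sites x days) with site ids as row names, day
#'   dates as column names, and attributes \code{species_id} and \code{year}.
#' @export
build_daily_matrix <- function(events, deployments, species_id, year) {
  events <- .normalize_dates(events, "date")
  deployments <- .normalize_dates(deployments, c("start_date", "end_date"))
  dep <- deployments[format(deployments$start_date, "%Y") == as.character(year), , drop = FALSE]
  if (!nrow(dep)) stop(sprintf("no deployments start in year %s", year))
  if (any(dep$end_date < dep$start_date)) stop("deployment with end_date before start_date")
  .check_overlaps(dep)
  sites <- sort(unique(dep$site_id))
  day0 <- min(dep$start_date)
  day1 <- max(dep$end_date)
  days <- seq(day0, day1, by = "day")
  m <- matrix(NA_integer_, length(sites), length(days),
              dimnames = list(sites, format(days)))
  for (i in seq_len(nrow(dep))) {
    j <- match(dep$site_id[i], sites)
    cols <- seq(as.integer(dep$start_date[i] - day0) + 1L,
                as.integer(dep$end_date[i] - day0) + 1L)
    m[j, cols] <- 0L
  }
  ev <- events[events$species_id == species_id &
                 format(events$date, "%Y") == as.character(year), , drop = FALSE]
  if (nrow(ev)) {
    unknown <- setdiff(ev$site_id, sites)
    if (length(unknown))
      stop(sprintf("event at unknown site '%s'", unknown[1L]))
    j <- match(ev$site_id, sites)
    k <- as.integer(ev$date - day0) + 1L
    if (any(k < 1L | k > length(days)))
      stop("event date outside the deployment window for its year")
    idx <- cbind(j, k)
    inactive <- is.na(m[idx])
    if (any(inactive)) {
      b <- which(inactive)[1L]
      stop(sprintf("event for '%s' at site '%s' on %s, but the camera was not active",
                   species_id, ev$site_id[b], format(ev$date[b])))
    }
    m[idx] <- 1L
  }
  attr(m, "species_id") <- species_id
  attr(m, "year") <- year
  attr(m, "unit") <- "day"
  m
}

.normalize_dates <- function(df, cols) {
  df <- as.data.frame(df)
  for (cl in cols) {
    if (!cl %in% names(df)) stop(sprintf("missing column '%s'", cl))
    df[[cl]] <- as.Date(df[[cl]])
    if (any(is.na(df[[cl]]))) stop(sprintf("unparseable dates in '%s'", cl))
  }
  df
}

.check_overlaps <- function(dep) {
  for (s in unique(dep$site_id)) {
    iv <- dep[dep$site_id == s, , drop = FALSE]
    if (nrow(iv) < 2L) next
    iv <- iv[order(iv$start_date), ]
    if (any(iv$start_date[-1L] <= iv$end_date[-nrow(iv)]))
      stop(sprintf("overlapping deployment intervals at site '%s'", s))
  }
}

#' Collapse a daily matrix into sampling periods
#'
#' Partitions the day columns into \code{n_periods} contiguous blocks, as
#' equal in size as possible (remainder days go one each to the earliest
#' blocks). A period is 1 if any day in its block is 1, 0 if no day is 1 but
#' at least one day was sampled, and \code{NA} only when every day in the
#' block is \code{NA}. Observations stay binary after grouping; only the
#' time unit of the detection probability changes.
#'
#' @param daily Sites-x-days ternary matrix (as from [build_daily_matrix]).
#' @param n_periods Number of periods; default 15.
#' @return Sites-x-periods integer matrix with the input's attributes.
#' @export
collapse_to_periods <- function(daily, n_periods = 15L) {
  n_periods <- as.integer(n_periods)
  if (n_periods < 1L) stop("`n_periods` must be at least 1")
  nd <- ncol(daily)
  if (nd < n_periods) stop("fewer days than periods")
  base <- nd %/% n_periods
  rem <- nd %% n_periods
  sizes <- rep(base, n_periods) + rep(c(1L, 0L), c(rem, n_periods - rem))
  block <- rep(seq_len(n_periods), sizes)
  out <- matrix(NA_integer_, nrow(daily), n_periods,
                dimnames = list(rownames(daily), NULL))
  for (k in seq_len(n_periods)) {
    sub <- daily[, block == k, drop = FALSE]
    any1 <- rowSums(sub == 1, na.rm = TRUE) > 0
    sampled <- rowSums(!is.na(sub)) > 0
    out[, k] <- ifelse(any1, 1L, ifelse(sampled, 0L, NA_integer_))
  }
  for (a in c("species_id", "year")) attr(out, a) <- attr(daily, a)
  attr(out, "unit") <- "period"
  out
}

#' Pool detection matrices across species
#'
#' Cell-wise union of detections across matched matrices (same sites, same
#' columns, same year): 1 if any input is 1, \code{NA} only where all inputs
#' are \code{NA}, else 0. Used to combine records of rarely detected species
#' (e.g. all cats) into one analysis unit.
#'
#' @param matrices List of ternary detection matrices of identical shape.
#' @param species_id Label for the pooled matrix.
#' @return Pooled ternary matrix.
#' @export
pool_species <- function(matrices, species_id = "pooled") {
  if (is.matrix(matrices)) matrices <- list(matrices)
  if (!length(matrices)) stop("`matrices` must be non-empty")
  dims <- vapply(matrices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("matrices have mismatched shapes")
  any1 <- Reduce(`+`, lapply(matrices, function(m) (!is.na(m)) & m == 1)) > 0
  anyS <- Reduce(`+`, lapply(matrices, function(m) !is.na(m))) > 0
  out <- ifelse(any1, 1L, ifelse(anyS, 0L, NA_integer_))
  dimnames(out) <- dimnames(matrices[[1L]])
  for (a in c("year", "unit")) attr(out, a) <- attr(matrices[[1L]], a)
  attr(out, "species_id") <- species_id
  out
}

#' Standardize site covariates
#'
#' Centers and scales every numeric covariate to sample mean 0 and standard
#' deviation 1, and expands categorical columns into 0/1 indicator columns
#' with the alphabetically first level as the reference. Scaling constants
#' are stored so coefficients can be mapped back to the original units.
#'
#' @param cov Data frame with a \code{site_id} column (kept as-is), numeric
#'   covariates and optional factor/character covariates.
#' @return Data frame of standardized covariates with attribute
#'   \code{scaling} (a data frame of column, center, scale).
#' @export
standardize_covariates <- function(cov) {
  cov <- as.data.frame(cov)
  out <- cov[intersect("site_id", names(cov))]
  scaling <- NULL
  for (nm in setdiff(names(cov), "site_id")) {
    v <- cov[[nm]]
    if (is.numeric(v)) {
      if (any(!is.finite(v))) stop(sprintf("non-finite values in covariate '%s'", nm))
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0)
        stop(sprintf("covariate '%s' has zero variance and cannot be standardized", nm))
      out[[nm]] <- (v - mean(v)) / s
      scaling <- rbind(scaling, data.frame(column = nm, center = mean(v), scale = s))
    } else {
      f <- factor(v, levels = sort(unique(as.character(v))))
      if (nlevels(f) < 2L)
        stop(sprintf("covariate '%s' has a single level", nm))
      for (lv in levels(f)[-1L])
        out[[paste(nm, lv, sep = "_")]] <- as.integer(f == lv)
    }
  }
  attr(out, "scaling") <- scaling
  out
}

#' Naive (uncorrected) annual occupancy
#'
#' Fraction of sampled sites with at least one detection in the year; sites
#' with no sampled period are excluded from the denominator. This is the
#' detection-biased quantity the occupancy model corrects.
#'
#' @param matrix Ternary sites-x-periods matrix for one year.
#' @return A proportion in \[0, 1\].
#' @export
naive_occupancy <- function(matrix) {
  sampled <- rowSums(!is.na(matrix)) > 0
  if (!any(sampled)) stop("no site was sampled")
  mean(rowSums(matrix[sampled, , drop = FALSE] == 1, na.rm = TRUE) > 0)
}

# --- CSV interfaces -------------------------------------------------------

#' Read camera-trap input tables
#'
#' Thin, validating readers for the four CSV inputs: detection events
#' (`species_id,site_id,date`), deployments
#' (`site_id,start_date,end_date`), site covariates (`site_id,...`) and
#' species attributes (`species_id,body_mass_kg,guild,hunted,iucn_status`).
#' Dates are ISO-8601. Lines starting with `#` are ignored.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @name read_tables
NULL

#' @rdname read_tables
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  .require_cols(df, c("species_id", "site_id", "date"), path)
  .normalize_dates(df, "date")
}

#' @rdname read_tables
#' @export
read_deployments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  .require_cols(df, c("site_id", "start_date", "end_date"), path)
  .normalize_dates(df, c("start_date", "end_date"))
}

#' @rdname read_tables
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  .require_cols(df, "site_id", path)
  df
}

#' @rdname read_tables
#' @export
read_species_attributes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  .require_cols(df, c("species_id", "body_mass_kg", "guild", "hunted", "iucn_status"), path)
  df$hunted <- as.logical(df$hunted)
  df
}

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", path, paste(miss, collapse = ", ")))
  invisible(df)
}

#' Write / read a detection matrix as wide CSV
#'
#' Wide CSV with a `site_id` label column and the literal `NA` for
#' not-sampled cells; a round trip reproduces the matrix cell-exactly.
#' An optional leading `# key: value` header carries run metadata.
#'
#' @param matrix Ternary detection matrix with row names.
#' @param path Output path.
#' @param header Optional named character vector written as `# key: value`
#'   comment lines.
#' @export
write_detection_matrix <- function(matrix, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (a in c("species_id", "year", "unit")) {
    if (!is.null(attr(matrix, a))) header <- c(header, stats::setNames(as.character(attr(matrix, a)), a))
  }
  if (!is.null(header))
    writeLines(sprintf("# %s: %s", names(header), header), con)
  df <- data.frame(site_id = rownames(matrix), matrix, check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detection_matrix
#' @export
read_detection_matrix <- function(path) {
  hdr <- character()
  lines <- readLines(path, n = 10L)
  hdr <- lines[startsWith(lines, "# ")]
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$site_id
  for (ln in hdr) {
    kv <- sub("^# ", "", ln)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*: ?", "", kv)
    if (key %in% c("species_id", "unit")) attr(m, key) <- val
    if (key == "year") attr(m, key) <- as.integer(val)
  }
  m
}
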