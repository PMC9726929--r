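.cohort_columns <- c("donor_id", "age", "sex", "race", "ethnicity",
                     "dose_gy", "dose_rate_category",
                     "mc_count", "dic_count", "bn_count", "mn_count",
                     "mono_count")

#' Read a per-aliquot cohort table
#'
#' Reads a CSV of blood-aliquot records. Deposited tables may use different
#' headers (or carry only precomputed indices), so `column_map` remaps
#' external names onto the canonical schema, e.g.
#' `c(dose_gy = "Dose", mn_count = "Mi")`.
#'
#' @param path CSV file path.
#' @param column_map Named character vector: names are canonical column
#'   names, values are the names used in the file.
#' @return A `data.frame` in the canonical column order. Rows whose required
#'   numeric fields do not parse are dropped with a warning reporting the
#'   count.
#' @export
read_cohort <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      ext <- column_map[[canon]]
      if (!ext %in% names(df)) stop("mapped column not present in file: ", ext)
      names(df)[names(df) == ext] <- canon
    }
  }
  missing <- setdiff(c("donor_id", "age", "dose_gy"), names(df))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "))
  num_cols <- intersect(setdiff(.cohort_columns, "donor_id"), names(df))
  for (cl in num_cols) df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  bad <- rowSums(is.na(df[, intersect(c("age", "dose_gy"), names(df)), drop = FALSE])) > 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with unparseable required fields dropped")
    df <- df[!bad, , drop = FALSE]
  }
  keep <- c(intersect(.cohort_columns, names(df)),
            setdiff(names(df), .cohort_columns))
  df[, keep, drop = FALSE]
}

#' Remove aliquots with unreliable low cell counts
#'
#' Aliquots with fewer than `min_bn` binucleated cells or fewer than
#' `min_mc` monocentric chromosomes give unreliable CBMN or DCA indices and
#' are removed. The boundary is inclusive: exactly 20 cells is retained.
#' Records lacking the count columns pass through untouched with a warning
#' (a deposited table may be pre-filtered and carry only indices).
#'
#' @param records Cohort `data.frame`.
#' @param min_bn,min_mc Minimum binucleated-cell and monocentric-chromosome
#'   counts to retain an aliquot.
#' @return A list with `records` (retained rows) and `filter_log`, a list
#'   holding `n_input`, `n_retained`, `n_excluded` and a per-excluded-row
#'   `reasons` data.frame (`row`, `reason`).
#' @export
filter_low_counts <- function(records, min_bn = 20, min_mc = 20) {
  n_in <- nrow(records)
  if (!all(c("bn_count", "mc_count") %in% names(records))) {
    warning("count columns absent; records passed through unfiltered")
    log <- list(n_input = n_in, n_retained = n_in, n_excluded = 0L,
                reasons = data.frame(row = integer(), reason = character()),
                counts_missing = TRUE)
    return(list(records = records, filter_log = log))
  }
  low_bn <- records$bn_count < min_bn
  low_mc <- records$mc_count < min_mc
  excl <- low_bn | low_mc
  reason <- ifelse(low_bn & low_mc, "BN+MC", ifelse(low_bn, "BN", "MC"))
  log <- list(n_input = n_in,
              n_retained = sum(!excl),
              n_excluded = sum(excl),
              reasons = data.frame(row = which(excl),
                                   reason = reason[excl],
                                   stringsAsFactors = FALSE),
              counts_missing = FALSE)
  list(records = records[!excl, , drop = FALSE], filter_log = log)
}

#' Compute assay indices, including the linearized micronucleus index
#'
#' Adds `yield = dic/MC` (dicentrics per monocentric chromosome),
#' `mi_bn = Mi/BN` (micronuclei per binucleated cell) and the linearized
#' index `mi_bn_c = Mi/BN + (1/k) * MN/BN`, where MN is the mononucleated
#' cell count. The `(1/k) * MN/BN` term compensates the high-dose turnover
#' of the raw index: cell-cycle arrest removes scorable binucleated cells at
#' high dose, and the rising mononucleated fraction tracks that arrest.
#'
#' @param records Cohort `data.frame` with count columns.
#' @param k Linearization constant (> 0); see [calibrate_k()].
#' @param yield_denominator `"mc"` (default) divides dicentrics by
#'   monocentric chromosomes; `"total"` divides by all scored chromosomes
#'   (MC + 2 * dic).
#' @return `records` with columns `yield`, `mi_bn`, `mi_bn_c` added.
#' @export
compute_indices <- function(records, k = 70,
                            yield_denominator = c("mc", "total")) {
  yield_denominator <- match.arg(yield_denominator)
  if (k <= 0) stop("k must be > 0")
  need <- c("mc_count", "dic_count", "bn_count", "mn_count", "mono_count")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("count columns required to compute indices: ",
         paste(missing, collapse = ", "))
  if (any(records$bn_count <= 0) || any(records$mc_count <= 0))
    stop("zero denominators: BN and MC must be > 0 (filter low counts first)")
  denom <- switch(yield_denominator,
                  mc = records$mc_count,
                  total = records$mc_count + 2 * records$dic_count)
  records$yield <- records$dic_count / denom
  records$mi_bn <- records$mn_count / records$bn_count
  records$mi_bn_c <- records$mi_bn + (1 / k) * records$mono_count / records$bn_count
  records
}

#' Encode a model matrix of dose-reconstruction features
#'
#' One-hot encodes race (codes 0..4) and ethnicity (codes 0..2) without
#' dropping a reference level (tree models are insensitive; "unreported" is a
#' legitimate level, not missingness). The default predictor set is
#' age + race + ethnicity + yield + mi_bn + mi_bn_c; sex and the ordinal
#' dose-rate category are opt-in because dose-rate information is unavailable
#' in a field triage scenario and sex is usually removed by feature selection.
#'
#' @param records Cohort `data.frame` with indices computed.
#' @param include_dose_rate Add the ordinal `dose_rate_category` column.
#' @param include_sex Add the binary `sex` column.
#' @return A list of class `model_matrix` with `features` (numeric matrix),
#'   `dose` (target vector, Gy) and `registry` (feature names).
#' @export
encode_features <- function(records, include_dose_rate = FALSE,
                            include_sex = FALSE) {
  need <- c("age", "race", "ethnicity", "yield", "mi_bn", "mi_bn_c", "dose_gy")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("columns required for encoding: ", paste(missing, collapse = ", "))
  if (any(!records$race %in% 0:4)) stop("unknown race level")
  if (any(!records$ethnicity %in% 0:2)) stop("unknown ethnicity level")
  one_hot <- function(v, levels, prefix) {
    m <- sapply(levels, function(l) as.numeric(v == l))
    colnames(m) <- paste0(prefix, "_", levels)
    m
  }
  x <- cbind(age = records$age,
             one_hot(records$race, 0:4, "race"),
             one_hot(records$ethnicity, 0:2, "ethnicity"),
             yield = records$yield,
             mi_bn = records$mi_bn,
             mi_bn_c = records$mi_bn_c)
  if (include_sex) {
    if (!"sex" %in% names(records)) stop("sex column absent")
    x <- cbind(x, sex = records$sex)
  }
  if (include_dose_rate) {
    if (!"dose_rate_category" %in% names(records))
      stop("dose_rate_category column absent")
    x <- cbind(x, dose_rate_category = records$dose_rate_category)
  }
  if (anyNA(x)) stop("model matrix contains missing values")
  out <- list(features = x, dose = records$dose_gy, registry = colnames(x))
  class(out) <- "model_matrix"
  out
}

#' @export
print.model_matrix <- function(x, ...) {
  cat(sprintf("model_matrix: %d rows, %d features (%s)\n", nrow(x$features),
              ncol(x$features), paste(x$registry, collapse = ", ")))
  invisible(x)
}

# subset rows of a model_matrix
mm_rows <- function(mm, idx) {
  out <- list(features = mm$features[idx, , drop = FALSE],
              dose = mm$dose[idx], registry = mm$registry)
  class(out) <- "model_matrix"
  out
}

# drop named feature columns
mm_drop <- function(mm, drop) {
  keep <- setdiff(mm$registry, drop)
  if (length(keep) == 0) stop("cannot remove all features")
  out <- list(features = mm$features[, keep, drop = FALSE], dose = mm$dose,
              registry = keep)
  class(out) <- "model_matrix"
  out
}

#' Partition records into train / eval / test parts
#'
#' Random partition in the given fractions (default 1/4 training, 1/4
#' evaluation, 1/2 held-out testing), reproducible by seed. By default the
#' split is stratified by dose level, which keeps rare dose groups (e.g. a
#' handful of 4 Gy aliquots) represented in every part.
#'
#' @param records Cohort `data.frame` (or anything with rows).
#' @param fractions Length-3 numeric summing to 1: train, eval, test.
#' @param seed Integer seed.
#' @param stratify_by Optional vector (default `records$dose_gy`) defining
#'   strata; `NULL` for a fully random split.
#' @return A list of class `split_assignment` with `part` (factor
#'   train/eval/test per row), `fractions` and `seed`.
#' @export
split_data <- function(records, fractions = c(0.25, 0.25, 0.5), seed = 1L,
                       stratify_by = records$dose_gy) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be length 3 and sum to 1")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  n <- nrow(records)
  if (n < sum(fractions > 0)) stop("too few rows for the requested parts")
  set.seed(seed)
  labels <- c("train", "eval", "test")
  part <- character(n)
  strata <- if (is.null(stratify_by)) rep(1L, n) else stratify_by
  for (s in unique(strata)) {
    idx <- which(strata == s)
    m <- length(idx)
    # largest-remainder apportionment of m rows to the three parts
    raw <- fractions * m
    cnt <- floor(raw)
    rem <- m - sum(cnt)
    if (rem > 0) {
      ord <- order(raw - cnt, decreasing = TRUE)
      cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
    }
    part[sample(idx)] <- rep(labels, times = cnt)
  }
  out <- list(part = factor(part, levels = labels), fractions = fractions,
              seed = seed)
  class(out) <- "split_assignment"
  out
}

#' @export
print.split_assignment <- function(x, ...) {
  print(table(x$part))
  invisible(x)
}
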