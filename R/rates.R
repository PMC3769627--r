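#' Net diversification rate from standing richness and clade age
#'
#' The constant-rate, pure-birth (Yule) taxonomic likelihood estimate
#' of net diversification,
#' \deqn{r = (\ln N_1 - \ln N_0) / t,}
#' where \eqn{N_1} is standing taxonomic diversity (described extant
#' species assigned to the clade), \eqn{N_0} the initial diversity
#' (default 1), and \eqn{t} the clade age in Ma. With crown ages some
#' authors prefer the crown convention \eqn{N_0 = 2}; pass `n0 = 2`
#' for that variant.
#'
#' @param n1 extant species count(s), `n1 >= n0`.
#' @param t clade age(s) in Ma, `t > 0`.
#' @param n0 initial diversity, default 1.
#' @return Net diversification rate in speciation events per lineage
#'   per Ma. Vectorized over `n1` and `t`.
#' @examples
#' net_rate(67, 3.83)   # ~1.098 sp/Ma
#' @export
net_rate <- function(n1, t, n0 = 1) {
  if (any(t <= 0)) stop("clade age t must be > 0", call. = FALSE)
  if (any(n0 < 1)) stop("initial diversity n0 must be >= 1", call. = FALSE)
  if (any(n1 < n0))
    stop("n1 < n0: net rate would be negative (not meaningful here)",
         call. = FALSE)
  (log(n1) - log(n0)) / t
}

#' Per-clade net diversification rates from a clade table
#'
#' For each clade, the rate is computed three times: from the mean age
#' (`r_mean`), from the lower 95% HPD age bound (`r_max`; a younger age
#' gives a faster rate), and from the upper bound (`r_min`). HPD columns
#' may be absent or NA, in which case only `r_mean` is reported.
#'
#' @param clades data frame with columns `name`, `n_species`, `age_mean`
#'   and optionally `age_lower_hpd`, `age_upper_hpd` (ages in Ma).
#' @param n0 initial diversity passed to [net_rate()].
#' @return The input columns plus `r_mean`, `r_max`, `r_min`
#'   (per-lineage per Ma), rows in input order.
#' @seealso [hypericum_clades()] for the packaged example table.
#' @export
rate_table <- function(clades, n0 = 1) {
  clades <- validate_clade_table(clades)
  n <- nrow(clades)
  res <- clades
  res$r_mean <- NA_real_
  res$r_max <- NA_real_
  res$r_min <- NA_real_
  for (i in seq_len(n)) {
    ri <- try_rate(clades$n_species[i], clades$age_mean[i], n0, clades$name[i], "age_mean")
    res$r_mean[i] <- ri
    if ("age_lower_hpd" %in% names(clades) && !is.na(clades$age_lower_hpd[i]))
      res$r_max[i] <- try_rate(clades$n_species[i], clades$age_lower_hpd[i], n0,
                               clades$name[i], "age_lower_hpd")
    if ("age_upper_hpd" %in% names(clades) && !is.na(clades$age_upper_hpd[i]))
      res$r_min[i] <- try_rate(clades$n_species[i], clades$age_upper_hpd[i], n0,
                               clades$name[i], "age_upper_hpd")
  }
  res
}

try_rate <- function(n1, t, n0, clade, field) {
  tryCatch(net_rate(n1, t, n0),
           error = function(e) stop("clade '", clade, "' (", field, "): ",
                                    conditionMessage(e), call. = FALSE))
}

#' Validate a clade table
#'
#' Checks the schema shared by [rate_table()] and [test_exceptional()]:
#' required columns, positive integer richness, positive ages, and
#' HPD bounds bracketing the mean where present. Errors report the
#' offending rows; nothing is silently dropped.
#'
#' @param clades data frame to validate.
#' @return The validated data frame (types coerced), invisibly usable.
#' @export
validate_clade_table <- function(clades) {
  if (!is.data.frame(clades)) stop("clades must be a data frame", call. = FALSE)
  need <- c("name", "n_species", "age_mean")
  miss <- setdiff(need, names(clades))
  if (length(miss))
    stop("clade table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(clades) == 0L) return(clades)
  clades$name <- as.character(clades$name)
  clades$n_species <- as.numeric(clades$n_species)
  clades$age_mean <- as.numeric(clades$age_mean)
  problems <- character(0)
  bad_row <- function(rows, msg)
    if (any(rows)) sprintf("row %s: %s", which(rows), msg) else character(0)
  problems <- c(
    problems,
    bad_row(is.na(clades$n_species) | clades$n_species < 1 |
              clades$n_species != round(clades$n_species),
            "n_species must be an integer >= 1"),
    bad_row(is.na(clades$age_mean) | clades$age_mean <= 0,
            "age_mean must be > 0")
  )
  if (all(c("age_lower_hpd", "age_upper_hpd") %in% names(clades))) {
    lo <- as.numeric(clades$age_lower_hpd)
    hi <- as.numeric(clades$age_upper_hpd)
    has <- !is.na(lo) & !is.na(hi)
    problems <- c(problems,
      bad_row(has & !(lo > 0 & lo <= clades$age_mean & clades$age_mean <= hi),
              "HPD bounds must satisfy 0 < lower <= mean <= upper"))
    clades$age_lower_hpd <- lo
    clades$age_upper_hpd <- hi
  }
  if (length(problems))
    stop("invalid clade table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  clades
}

#' Read a clade table from a delimited file
#'
#' @param file tab-delimited file with columns `name`, `n_species`,
#'   `age_mean`, and optional `age_lower_hpd`, `age_upper_hpd`.
#' @return Validated clade table.
#' @export
read_clade_table <- function(file) {
  validate_clade_table(utils::read.delim(file, stringsAsFactors = FALSE,
                                         check.names = FALSE))
}

#' Crown ages and species richness of New World Hypericum clades
#'
#' The seven major clades of New World *Hypericum* with their standing
#' species richness and Bayesian relaxed-clock crown age estimates
#' (mean and 95% HPD bounds, Ma), as published. The
#' `Triadenum+Myriandra+Brathys s.l.` row is the whole phylogeny and
#' provides the background diversification rate for the exceptional
#' richness test; `Páramo` is the focal high-Andean clade.
#'
#' @return Clade table data frame (7 rows).
#' @examples
#' rate_table(hypericum_clades())
#' @export
hypericum_clades <- function() {
  path <- system.file("extdata", "hypericum_clades.tsv", package = "divrich",
                      mustWork = TRUE)
  read_clade_table(path)
}
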