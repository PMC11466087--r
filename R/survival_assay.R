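#' Construct a CFU survival assay
#'
#' Holds colony-forming-unit counts from an acute-exposure survival
#' experiment: per biological replicate, technical-replicate plate counts for
#' the sham (0 Gy) control and for each dose, all adjusted to the same
#' dilution/plating factor.
#'
#' @param biological_replicates List; each element is a list with
#'   `sham_counts` (non-empty numeric vector of positive counts at 0 Gy) and
#'   `dosed_counts` (named list mapping dose in Gy, as the name, to a numeric
#'   vector of counts).
#' @return An object of class `survival_assay`.
#' @export
survival_assay <- function(biological_replicates) {
  stopifnot(is.list(biological_replicates), length(biological_replicates) >= 1L)
  for (i in seq_along(biological_replicates)) {
    br <- biological_replicates[[i]]
    if (!is.list(br) || !all(c("sham_counts", "dosed_counts") %in% names(br))) {
      stop("biological replicate ", i,
           " needs fields sham_counts and dosed_counts", call. = FALSE)
    }
    if (length(br$sham_counts) == 0L || any(br$sham_counts < 0)) {
      stop("biological replicate ", i,
           ": sham_counts must be non-empty and non-negative", call. = FALSE)
    }
    doses <- as.numeric(names(br$dosed_counts))
    if (length(doses) > 0L && (any(is.na(doses)) || any(doses <= 0))) {
      stop("biological replicate ", i,
           ": dosed_counts names must be positive doses in Gy", call. = FALSE)
    }
  }
  structure(list(biological_replicates = biological_replicates),
            class = "survival_assay")
}

#' Read a CFU assay CSV
#'
#' Format: columns `biological_rep`, `dose_gy`, `technical_rep`, `cfu_count`;
#' rows with `dose_gy == 0` are the sham controls.
#'
#' @param path Path to the CSV.
#' @return A [survival_assay()].
#' @export
read_assay_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("biological_rep", "dose_gy", "technical_rep", "cfu_count")
  if (!all(needed %in% names(df))) {
    stop("assay CSV needs columns ", paste(needed, collapse = ", "),
         "; found: ", paste(names(df), collapse = ", "), call. = FALSE)
  }
  reps <- lapply(split(df, df$biological_rep), function(rows) {
    sham <- rows$cfu_count[rows$dose_gy == 0]
    dosed <- rows[rows$dose_gy > 0, , drop = FALSE]
    list(
      sham_counts = sham,
      dosed_counts = lapply(split(dosed$cfu_count, dosed$dose_gy), as.numeric)
    )
  })
  survival_assay(unname(reps))
}

#' Write a CFU assay CSV
#'
#' Inverse of [read_assay_csv()].
#'
#' @param assay A [survival_assay()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(assay, path) {
  stopifnot(inherits(assay, "survival_assay"))
  rows <- list()
  for (b in seq_along(assay$biological_replicates)) {
    br <- assay$biological_replicates[[b]]
    rows[[length(rows) + 1L]] <- data.frame(
      biological_rep = b, dose_gy = 0,
      technical_rep = seq_along(br$sham_counts), cfu_count = br$sham_counts
    )
    for (d in names(br$dosed_counts)) {
      counts <- br$dosed_counts[[d]]
      rows[[length(rows) + 1L]] <- data.frame(
        biological_rep = b, dose_gy = as.numeric(d),
        technical_rep = seq_along(counts), cfu_count = counts
      )
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Surviving fractions from a CFU assay
#'
#' Within each biological replicate, the baseline is the mean of the sham
#' (0 Gy) technical-replicate counts, and every dosed technical replicate
#' yields `count / baseline`. Fractions may exceed 1 (plating noise).
#'
#' @param assay A [survival_assay()].
#' @return Data frame with columns `dose_gy`, `fraction`, `biological_rep`.
#' @export
surviving_fraction <- function(assay) {
  stopifnot(inherits(assay, "survival_assay"))
  out <- list()
  for (b in seq_along(assay$biological_replicates)) {
    br <- assay$biological_replicates[[b]]
    baseline <- mean(br$sham_counts)
    if (baseline <= 0) {
      stop("biological replicate ", b,
           ": sham mean is 0, surviving fraction undefined", call. = FALSE)
    }
    for (d in names(br$dosed_counts)) {
      counts <- br$dosed_counts[[d]]
      out[[length(out) + 1L]] <- data.frame(
        dose_gy = as.numeric(d), fraction = counts / baseline,
        biological_rep = b
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(dose_gy = numeric(0), fraction = numeric(0),
                      biological_rep = integer(0)))
  }
  do.call(rbind, out)
}

#' Fit a D10 from dose-survival points
#'
#' Default model: the classical single-hit exponential survival curve,
#' `log10(S) = -dose / D10`, fit by least squares through the origin
#' (zero-dose survival is 1 by construction, since fractions are already
#' sham-baselined). D10 — the decimal reduction dose — is `-1/slope`.
#' Points with fraction <= 0 cannot enter a log fit and are dropped with a
#' warning.
#'
#' An optional two-parameter logistic alternative
#' (`S = 1 / (1 + exp((log(d) - a) / b))`, fit by nonlinear least squares) is
#' available via `model = "logistic"`; its D10 is the dose where the fitted
#' curve crosses 0.1. Either way, `slope_per_gy` reports the equivalent
#' log-linear inactivation rate `-1/D10`.
#'
#' @param points Data frame with columns `dose_gy` (or `dose`) and
#'   `fraction`, e.g. from [surviving_fraction()].
#' @param model `"loglinear"` (default) or `"logistic"`.
#' @return An object of class `d10_fit`: `d10_gy`, `slope_per_gy`
#'   (`= -1/d10_gy`), `fit_points`, `residual_sd` (in log10 units for the
#'   default model), `n_dropped` and `model`.
#' @export
fit_d10 <- function(points, model = c("loglinear", "logistic")) {
  model <- match.arg(model)
  if (!is.data.frame(points)) points <- as.data.frame(points)
  dose_col <- intersect(c("dose_gy", "dose"), names(points))[1L]
  if (is.na(dose_col) || !"fraction" %in% names(points)) {
    stop("points needs columns dose_gy (or dose) and fraction", call. = FALSE)
  }
  dose <- as.numeric(points[[dose_col]])
  frac <- as.numeric(points$fraction)
  if (any(dose <= 0)) stop("doses must be positive (sham rows are baselines, not points)",
                           call. = FALSE)
  drop <- frac <= 0
  n_dropped <- sum(drop)
  if (n_dropped > 0L) {
    warning("dropped ", n_dropped,
            " point(s) with surviving fraction <= 0 (zero-count plates)",
            call. = FALSE)
  }
  dose <- dose[!drop]
  frac <- frac[!drop]
  if (length(dose) == 0L) {
    stop("no points with positive surviving fraction; cannot fit", call. = FALSE)
  }

  if (model == "loglinear") {
    ly <- log10(frac)
    slope <- sum(dose * ly) / sum(dose^2)
    if (slope >= 0) {
      stop("no dose-dependent killing detected (fitted slope >= 0)",
           call. = FALSE)
    }
    d10 <- -1 / slope
    resid <- ly - slope * dose
    residual_sd <- if (length(resid) > 1L) stats::sd(resid) else 0
  } else {
    if (length(unique(dose)) < 2L) {
      stop("logistic fit needs at least 2 distinct doses", call. = FALSE)
    }
    ## seed the nonlinear fit from the log-linear solution
    slope0 <- min(sum(dose * log10(frac)) / sum(dose^2), -1e-8)
    a0 <- log(-1 / slope0) + log(9)   # logistic crosses 0.1 at d = exp(a + b log 9) with b = 1
    fit <- stats::nls(frac ~ 1 / (1 + exp((log(dose) - a) / b)),
                      start = list(a = a0, b = 1),
                      control = stats::nls.control(warnOnly = TRUE))
    cf <- stats::coef(fit)
    if (cf[["b"]] <= 0) {
      stop("no dose-dependent killing detected (logistic slope inverted)",
           call. = FALSE)
    }
    d10 <- exp(cf[["a"]] + cf[["b"]] * log(9))
    resid <- stats::resid(fit)
    residual_sd <- if (length(resid) > 1L) stats::sd(resid) else 0
  }

  structure(
    list(d10_gy = d10, slope_per_gy = -1 / d10,
         fit_points = data.frame(dose_gy = dose, fraction = frac),
         residual_sd = residual_sd, n_dropped = n_dropped, model = model),
    class = "d10_fit"
  )
}

#' @export
print.d10_fit <- function(x, ...) {
  cat(sprintf("<d10_fit> D10 = %.4g Gy (%s model, %d points, residual sd %.3g)\n",
              x$d10_gy, x$model, nrow(x$fit_points), x$residual_sd))
  invisible(x)
}

#' Predicted surviving fraction under the fitted survival curve
#'
#' Under the log-linear model, survival at dose `d` is `10^(-d / D10)`: 1 at
#' 0 Gy, 0.1 at the D10 by definition, 0.01 at twice the D10.
#'
#' @param fit A `d10_fit`, or a bare positive number taken as a D10 in Gy.
#' @param dose Dose(s) in Gy, non-negative.
#' @return Surviving fraction(s) in (0, 1].
#' @export
predict_survival <- function(fit, dose) {
  d10 <- if (inherits(fit, "d10_fit")) fit$d10_gy else as.numeric(fit)
  if (!is.numeric(d10) || length(d10) != 1L || !is.finite(d10) || d10 <= 0) {
    stop("fit must be a d10_fit or a positive D10 in Gy", call. = FALSE)
  }
  if (any(dose < 0)) stop("dose must be non-negative", call. = FALSE)
  10^(-dose / d10)
}
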