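## qPCR-calibrated absolute quantification.
##
## Ct -> CFU conversion through fixed calibration curves, relative -> absolute
## read conversion (na = nr * Q / Nt), per-stratum log-log regression of
## absolute reads on qPCR loads, and per-species deviation statistics.

#' Convert threshold cycles to loads (and back)
#'
#' `CFU = exp((Ct - intercept) / slope)`; `cfu_to_ct` is the exact inverse.
#'
#' @param ct threshold cycle(s).
#' @param cfu load(s) in CFU.g^-1.
#' @param curve a [calibration_curve()].
#' @return numeric vector.
#' @examples
#' ct_to_cfu(39.43, calibration_curve("16S"))  # 1
#' @export
ct_to_cfu <- function(ct, curve = calibration_curve("16S")) {
  if (any(!is.finite(ct))) stop("Ct must be finite", call. = FALSE)
  exp((ct - curve$intercept) / curve$slope)
}

#' @rdname ct_to_cfu
#' @export
cfu_to_ct <- function(cfu, curve = calibration_curve("16S")) {
  if (any(cfu <= 0)) stop("CFU must be positive", call. = FALSE)
  curve$intercept + curve$slope * log(cfu)
}

#' Relative to absolute read counts
#'
#' `na = nr * Q / Nt`, where `Q` is the total bacterial load of the sample
#' (all-bacteria qPCR, CFU.g^-1) and `Nt` the normalized sum of reads in the
#' sample.
#'
#' @param nr relative (normalized) read count of the species, >= 0.
#' @param Q total load, > 0.
#' @param Nt normalized read total of the sample, > 0.
#' @return absolute read count(s).
#' @export
to_absolute <- function(nr, Q, Nt) {
  if (any(Nt <= 0)) stop("Nt must be > 0", call. = FALSE)
  if (any(Q <= 0)) stop("Q must be > 0", call. = FALSE)
  if (any(nr < 0)) stop("nr must be >= 0", call. = FALSE)
  nr * Q / Nt
}

#' Build per-species quantification records from pipeline output
#'
#' Aggregates (median-depth-normalized) species read counts, converts the
#' per-sample all-bacteria Ct to a total load Q, and applies
#' [to_absolute()]; per-species qPCR Cts are converted to CFU with the
#' housekeeping curve.
#'
#' @param otus a filtered `otutab`.
#' @param assignments matching [assign_taxonomy()] output.
#' @param qpcr `data.frame(sample, species, Ct, curve_id)` as produced by
#'   [simulate_qpcr()]; must contain `all_bacteria` rows.
#' @param normalize median-depth-normalize the table first (default `TRUE`).
#' @return `data.frame(species, sample, phylum, marker, nr, Q, Nt, na, cfu)`;
#'   species with `nr = 0` have `na = 0` and are flagged `detected = FALSE`.
#' @export
quant_records <- function(otus, assignments, qpcr, normalize = TRUE) {
  stopifnot(inherits(otus, "otutab"))
  tab <- if (normalize) median_depth_normalize(otus) else otus
  counts <- tab$counts
  a <- assignments[match(rownames(counts), assignments$otu_id), ]
  qp <- qpcr[qpcr$species != "all_bacteria", , drop = FALSE]
  qall <- qpcr[qpcr$species == "all_bacteria", , drop = FALSE]
  if (!nrow(qall)) stop("qpcr lacks all_bacteria measurements", call. = FALSE)
  curve_hk <- calibration_curve("housekeeping")
  curve_16s <- calibration_curve("16S")
  Q <- setNames(ct_to_cfu(qall$Ct, curve_16s), qall$sample)
  Nt <- colSums(counts)
  rows <- lapply(seq_len(nrow(qp)), function(i) {
    sp <- qp$species[i]; smp <- qp$sample[i]
    if (!smp %in% colnames(counts) || !smp %in% names(Q)) return(NULL)
    sel <- !is.na(a$species) & a$species == sp
    nr <- sum(counts[sel, smp])
    phy <- mock_strain_table()$tax[[sp]][["phylum"]]
    data.frame(species = sp, sample = smp,
               phylum = if (is.null(phy)) NA_character_ else phy,
               marker = "gyrB", nr = nr, Q = unname(Q[smp]),
               Nt = unname(Nt[smp]),
               na = to_absolute(nr, Q[[smp]], Nt[[smp]]),
               cfu = ct_to_cfu(qp$Ct[i], curve_hk),
               detected = nr > 0, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Fit the log-log quantification model for one stratum
#'
#' Ordinary least squares of `log10(na)` on `log10(cfu)` over the records of
#' one phylum x marker stratum; zero-read species are excluded (log
#' undefined) and reported as not detected.
#'
#' @param records rows of [quant_records()] (one stratum).
#' @param stratum optional label stored with the fit.
#' @return object of class `quantfit` with components `slope`, `intercept`,
#'   `r_squared`, `residuals` (log10 units, named by species:sample),
#'   `data`, `stratum` and the underlying `lm` fit.
#' @export
fit_quant_model <- function(records, stratum = NULL) {
  rec <- records[records$nr > 0, , drop = FALSE]
  if (nrow(rec) < 3L)
    stop("need at least 3 detected records to fit the quantification model",
         call. = FALSE)
  df <- data.frame(x = log10(rec$cfu), y = log10(rec$na))
  fit <- lm(y ~ x, data = df)
  res <- setNames(residuals(fit), paste(rec$species, rec$sample, sep = ":"))
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 residuals = res, data = rec, stratum = stratum, lm = fit),
            class = "quantfit")
}

#' @export
print.quantfit <- function(x, ...) {
  cat(sprintf("quantfit%s: log10(na) = %.3f + %.3f log10(CFU), r^2 = %.3f, n = %d\n",
              if (is.null(x$stratum)) "" else paste0(" [", x$stratum, "]"),
              x$intercept, x$slope, x$r_squared, nrow(x$data)))
  invisible(x)
}

#' @export
coef.quantfit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.quantfit <- function(object, ...) object$residuals

#' @export
predict.quantfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(predict(object$lm))
  cfu <- if (is.data.frame(newdata)) newdata$cfu else newdata
  unname(predict(object$lm, newdata = data.frame(x = log10(cfu))))
}

#' @export
summary.quantfit <- function(object, ...) {
  s <- suppressWarnings(summary(object$lm))
  cat(sprintf("Quantification model%s\n",
              if (is.null(object$stratum)) ""
              else paste0(" — stratum ", object$stratum)))
  cat(sprintf("  slope %.4f, intercept %.4f, r^2 %.4f, n %d\n",
              object$slope, object$intercept, object$r_squared,
              nrow(object$data)))
  cat(sprintf("  residual sd %.4f log10 units\n", s$sigma))
  invisible(s)
}

#' @export
plot.quantfit <- function(x, ...) {
  plot(log10(x$data$cfu), log10(x$data$na),
       xlab = "log10 qPCR load (CFU/g)", ylab = "log10 absolute reads",
       main = if (is.null(x$stratum)) "quantfit" else x$stratum, ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Per-species deviation from the quantification model
#'
#' Deviation of each observation is `log10(na) - fitted`; per species the
#' signed median, the median absolute deviation from the line and a sign
#' call are reported (`"unbiased"` within +/- `band` log10 units,
#' `"overestimated"` above, `"underestimated"` below).
#'
#' @param fit a [fit_quant_model()] object.
#' @param band half-width of the unbiased call band in log10 units
#'   (default 0.1).
#' @return `data.frame(species, n, median_deviation, median_abs_deviation,
#'   call)`.
#' @export
species_deviation <- function(fit, band = 0.1) {
  stopifnot(inherits(fit, "quantfit"))
  sp <- fit$data$species
  dev <- unname(fit$residuals)
  rows <- lapply(sort(unique(sp)), function(s) {
    d <- dev[sp == s]
    m <- median(d)
    data.frame(species = s, n = length(d), median_deviation = m,
               median_abs_deviation = median(abs(d)),
               call = if (abs(m) < band) "unbiased"
                      else if (m > 0) "overestimated" else "underestimated",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Fit quantification models for every phylum x marker stratum
#'
#' @param records full [quant_records()] output.
#' @param min_points strata with fewer detected points are skipped with a
#'   message.
#' @return named list of `quantfit` objects.
#' @export
fit_quant_strata <- function(records, min_points = 3L) {
  key <- paste(records$phylum, records$marker, sep = ":")
  out <- list()
  for (k in unique(key)) {
    rec <- records[key == k, , drop = FALSE]
    if (sum(rec$nr > 0) < min_points) {
      message("stratum ", k, " skipped (<", min_points, " detected points)")
      next
    }
    out[[k]] <- fit_quant_model(rec, stratum = k)
  }
  out
}
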