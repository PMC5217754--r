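#' Assemble the six plot-level model covariates
#'
#' The convergence rates of the flux models are driven by six covariates:
#' `loss` (disturbance intensity, \% of pre-logging ACS lost), `acs0` (site
#' mean pre-logging ACS, Mg C ha^-1), `dacs` (plot pre-logging ACS as a \%
#' deviation from `acs0`, a forest-maturity proxy), `prec` (annual
#' precipitation, mm), `seas` (precipitation seasonality) and `bd` (topsoil
#' bulk density, g cm^-3). The first three derive from the flux decomposition;
#' the last three are site-level environmental variables supplied tabularly.
#'
#' @param meta per-plot metadata, e.g. [flux_meta()] output: columns
#'   `plot_id`, `site_id`, `acs_prelogging`, `loss`.
#' @param site_table data.frame with columns `site_id`, `prec`, `seas`, `bd`.
#' @return data.frame with one row per plot and columns `plot_id`, `site_id`,
#'   `loss`, `acs0`, `dacs`, `prec`, `seas`, `bd`.
#' @export
build_covariates <- function(meta, site_table) {
  need <- c("site_id", "prec", "seas", "bd")
  miss <- setdiff(need, names(site_table))
  if (length(miss))
    stop("site table is missing columns: ", paste(miss, collapse = ", "))
  acs0_site <- tapply(meta$acs_prelogging, meta$site_id, mean)
  out <- data.frame(plot_id = meta$plot_id, site_id = meta$site_id,
                    loss = meta$loss)
  out$acs0 <- as.numeric(acs0_site[as.character(meta$site_id)])
  out$dacs <- 100 * (meta$acs_prelogging - out$acs0) / out$acs0
  m <- match(out$site_id, site_table$site_id)
  if (anyNA(m))
    stop("no site covariates for site(s): ",
         paste(unique(out$site_id[is.na(m)]), collapse = ", "))
  for (v in c("prec", "seas", "bd")) {
    out[[v]] <- site_table[[v]][m]
    if (anyNA(out[[v]]))
      stop("missing covariate '", v, "' for plot(s) ",
           paste(out$plot_id[is.na(out[[v]])], collapse = ", "))
  }
  out
}

#' Names of the six model covariates, in model order
#' @return character vector.
#' @export
covariate_names <- function() c("loss", "acs0", "dacs", "prec", "seas", "bd")

#' Centre and standardize covariates, storing calibration moments
#'
#' Each covariate is transformed to mean 0 and standard deviation 1 over the
#' calibration plots (sample sd, n - 1 denominator). The moments are stored so
#' that prediction-time inputs -- e.g. the mapped 40\%-loss scenario -- are
#' standardized on the calibration scale, never re-centred on the prediction
#' inputs.
#'
#' @param cov covariate data.frame from [build_covariates()].
#' @return object of class `acs_covariates`: the input data.frame with the six
#'   standardized columns (suffix `_z`) appended and a `moments` attribute
#'   (data.frame covariate/mean/sd).
#' @export
standardize_covariates <- function(cov) {
  vars <- covariate_names()
  stopifnot(all(vars %in% names(cov)))
  mom <- data.frame(covariate = vars, mean = NA_real_, sd = NA_real_,
                    min = NA_real_, max = NA_real_)
  for (i in seq_along(vars)) {
    x <- cov[[vars[i]]]
    if (length(unique(x)) < 2 || stats::sd(x) == 0)
      stop("covariate '", vars[i], "' has zero variance: uninformative")
    mom$mean[i] <- mean(x); mom$sd[i] <- stats::sd(x)
    mom$min[i] <- min(x); mom$max[i] <- max(x)
    cov[[paste0(vars[i], "_z")]] <- (x - mom$mean[i]) / mom$sd[i]
  }
  structure(cov, moments = mom, class = c("acs_covariates", "data.frame"))
}

#' Calibration moments of a standardized covariate set
#' @param cov an `acs_covariates` object.
#' @return data.frame with columns `covariate`, `mean`, `sd`.
#' @export
covariate_moments <- function(cov) attr(cov, "moments")

#' Standardize new covariate values with stored calibration moments
#'
#' @param newdata data.frame containing (a subset of) the six raw covariates.
#' @param moments a moments data.frame ([covariate_moments()]).
#' @return `newdata` with `_z` columns appended for every covariate present.
#' @export
apply_moments <- function(newdata, moments) {
  for (i in seq_len(nrow(moments))) {
    v <- moments$covariate[i]
    if (v %in% names(newdata))
      newdata[[paste0(v, "_z")]] <- (newdata[[v]] - moments$mean[i]) / moments$sd[i]
  }
  newdata
}

#' Invert standardization with stored moments
#' @param z numeric vector of standardized values.
#' @param covariate covariate name.
#' @param moments a moments data.frame.
#' @return raw-scale values.
#' @export
invert_moments <- function(z, covariate, moments) {
  i <- match(covariate, moments$covariate)
  if (is.na(i)) stop("unknown covariate '", covariate, "'")
  z * moments$sd[i] + moments$mean[i]
}

#' Persist covariates and calibration moments
#'
#' The covariate table is written as CSV and the moments as a YAML-like plain
#' text sidecar (`<path>_moments.txt`, `covariate mean sd` per line) so a
#' prediction run can reload them verbatim.
#'
#' @param cov an `acs_covariates` object.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(cov, path) {
  utils::write.csv(as.data.frame(cov), path, row.names = FALSE)
  utils::write.csv(covariate_moments(cov),
                   sub("\\.csv$", "_moments.csv", path), row.names = FALSE)
  invisible(path)
}

#' Reload covariates persisted by [write_covariates()]
#' @param path CSV path given to [write_covariates()].
#' @return an `acs_covariates` object.
#' @export
read_covariates <- function(path) {
  cov <- utils::read.csv(path, stringsAsFactors = FALSE)
  mom <- utils::read.csv(sub("\\.csv$", "_moments.csv", path),
                         stringsAsFactors = FALSE)
  structure(cov, moments = mom, class = c("acs_covariates", "data.frame"))
}
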