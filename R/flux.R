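#' Detect the start of the post-logging recovery period
#'
#' Plot carbon stocks keep falling for a few years after logging (delayed
#' mortality of damaged trees). The recovery period starts at the census with
#' the minimum ACS within `window` years after logging. Plots whose overall
#' post-logging minimum falls outside that window are excluded: the late
#' minimum indicates a disturbance unrelated to the logging event (fire, road
#' opening, silvicultural treatment) or a plot the logging never affected.
#'
#' @param census_time numeric vector of census dates (decimal years).
#' @param acs plot ACS (Mg C ha^-1) at each census.
#' @param logging_time date of the logging event.
#' @param window length of the search window after logging, years; default 4.
#' @return a list with `t0` (census time of minimum), `acs_min`, `excluded`
#'   (logical) and `reason` (`NA` or a character explanation).
#' @export
detect_recovery_start <- function(census_time, acs, logging_time, window = 4) {
  stopifnot(length(census_time) == length(acs))
  o <- order(census_time)
  census_time <- census_time[o]; acs <- acs[o]
  post <- census_time > logging_time
  if (!any(post))
    return(list(t0 = NA_real_, acs_min = NA_real_, excluded = TRUE,
                reason = "no post-logging census"))
  in_win <- post & census_time <= logging_time + window
  if (!any(in_win))
    return(list(t0 = NA_real_, acs_min = NA_real_, excluded = TRUE,
                reason = sprintf("no census within %g years of logging", window)))
  k <- which(in_win)[which.min(acs[in_win])]
  acs_min <- acs[k]
  late <- post & census_time > logging_time + window
  if (any(late) && min(acs[late]) < acs_min)
    return(list(t0 = NA_real_, acs_min = NA_real_, excluded = TRUE,
                reason = "post-logging ACS minimum reached after the window"))
  list(t0 = census_time[k], acs_min = acs_min, excluded = FALSE,
       reason = NA_character_)
}

#' Classify trees into survivor and recruit cohorts across one census interval
#'
#' Survivors are trees at or above the diameter threshold and alive at the
#' start of the recovery period; recruits cross the threshold afterwards.
#' Cohort membership is fixed at first threshold crossing and retained until
#' death: a recruit later measured below the threshold stays a recruit, and
#' trees that die without ever being recorded alive at or above the threshold
#' never enter either cohort.
#'
#' @param prev,curr data.frames for the two censuses (columns `tree_id`,
#'   `dbh`, `status`).
#' @param membership named character vector carrying cohort state
#'   (`tree_id -> "survivor"` or `"recruit"`) from earlier intervals; at the
#'   first interval pass the survivor assignment made at t0.
#' @param dbh_min diameter threshold, cm.
#' @return list with character vectors of tree ids: `survivors` (alive members
#'   at both ends), `new_recruits` (first crossing in this interval),
#'   `dead_survivors`, `dead_recruits`, and the updated `membership`.
#' @export
classify_cohorts <- function(prev, curr, membership, dbh_min = 20) {
  prev_alive <- prev$tree_id[prev$status == "alive"]
  curr_alive <- curr$tree_id[curr$status == "alive"]
  known <- names(membership)

  new_ids <- curr$tree_id[curr$status == "alive" & curr$dbh >= dbh_min &
                            !curr$tree_id %in% known]
  # deaths among established cohort members: alive at prev, not alive at curr
  # (absence from the current census is treated as death)
  dead <- intersect(known, prev_alive)
  dead <- dead[!dead %in% curr_alive]
  surv_live <- intersect(known[membership == "survivor"],
                         intersect(prev_alive, curr_alive))
  rec_live <- intersect(known[membership == "recruit"],
                        intersect(prev_alive, curr_alive))
  membership[new_ids] <- "recruit"
  list(survivors = surv_live,
       new_recruits = new_ids,
       dead_survivors = dead[membership[dead] == "survivor"],
       dead_recruits = dead[membership[dead] == "recruit"],
       recruits_alive = rec_live,
       membership = membership)
}

#' Five cohort carbon fluxes over one census interval
#'
#' Given the cohort classification of [classify_cohorts()] and the per-tree
#' carbon stocks at both censuses, computes the interval totals of the five
#' ACS changes in Mg C ha^-1: `Sg` survivors' growth, `Sl` survivors'
#' mortality loss, `Rr` carbon of first-time recruits, `Rg` growth of living
#' recruits, `Rl` recruits' mortality loss. Gains are non-negative and losses
#' non-positive; a net negative growth term (a measurement artifact) is
#' floored at zero with a warning. Trees that die are valued at their last
#' live census.
#'
#' @param prev,curr data.frames with columns `tree_id` and `acs` (Mg C).
#' @param cohorts result of [classify_cohorts()].
#' @param area plot area, ha.
#' @return named numeric vector `c(Rr, Rg, Rl, Sg, Sl)` in Mg C ha^-1.
#' @export
interval_fluxes <- function(prev, curr, cohorts, area = 1) {
  stopifnot(area > 0)
  a_prev <- stats::setNames(prev$acs, prev$tree_id)
  a_curr <- stats::setNames(curr$acs, curr$tree_id)
  inc <- function(ids) if (length(ids)) sum(a_curr[ids] - a_prev[ids]) else 0
  Sg <- inc(cohorts$survivors)
  Rg <- inc(cohorts$recruits_alive)
  Rr <- if (length(cohorts$new_recruits)) sum(a_curr[cohorts$new_recruits]) else 0
  Sl <- if (length(cohorts$dead_survivors)) -sum(a_prev[cohorts$dead_survivors]) else 0
  Rl <- if (length(cohorts$dead_recruits)) -sum(a_prev[cohorts$dead_recruits]) else 0
  if (Sg < 0) { warning("net negative survivors' growth floored at 0"); Sg <- 0 }
  if (Rg < 0) { warning("net negative recruits' growth floored at 0"); Rg <- 0 }
  c(Rr = Rr, Rg = Rg, Rl = Rl, Sg = Sg, Sl = Sl) / area
}

#' Cumulative flux series from interval fluxes
#'
#' Running sums of the five interval series, zero at the start of the recovery
#' period, in Mg C ha^-1.
#'
#' @param flux data.frame with columns `Rr`, `Rg`, `Rl`, `Sg`, `Sl`, ordered
#'   in time, first row at t = 0 (all zeros).
#' @return the same data.frame with columns `cRr`, `cRg`, `cRl`, `cSg`, `cSl`
#'   appended.
#' @export
cumulative_fluxes <- function(flux) {
  for (v in c("Rr", "Rg", "Rl", "Sg", "Sl"))
    flux[[paste0("c", v)]] <- cumsum(flux[[v]])
  flux
}

#' Disturbance intensity of a plot
#'
#' Percentage of the pre-logging carbon stock lost by the start of the
#' recovery period: `100 * (acs_prelogging - acs_min) / acs_prelogging`.
#'
#' @param acs_prelogging pre-logging plot ACS, Mg C ha^-1.
#' @param acs_min minimum post-logging ACS (start of recovery).
#' @param clamp if `TRUE` (default) a negative loss (post-logging stock above
#'   the pre-logging stock, a measurement artifact) is clamped to 0 with a
#'   warning; if `FALSE` the negative value is returned as-is.
#' @return loss in percent.
#' @export
disturbance_intensity <- function(acs_prelogging, acs_min, clamp = TRUE) {
  stopifnot(acs_prelogging > 0)
  loss <- 100 * (acs_prelogging - acs_min) / acs_prelogging
  neg <- loss < 0
  if (any(neg) && clamp) {
    warning("negative disturbance intensity clamped to 0")
    loss[neg] <- 0
  }
  loss
}

# per-tree ACS for every row of an inventory (one site's E per plot)
.inventory_acs <- function(inv, table, sites, dbh_min, carbon_fraction) {
  E_of <- stats::setNames(sites$E, sites$site_id)
  inv$acs <- NA_real_
  ok <- inv$status == "alive" & inv$dbh > 0
  if (any(ok)) {
    for (sid in unique(inv$site_id[ok])) {
      sel <- ok & inv$site_id == sid
      wd <- assign_wood_density_all(inv[sel, , drop = FALSE], table, sid)
      inv$acs[sel] <- tree_acs(inv$dbh[sel], wd, E_of[[as.character(sid)]],
                               carbon_fraction)
    }
  }
  inv
}

#' Decompose plot inventories into the five-flux recovery series
#'
#' The full accounting pipeline: per-tree carbon via [tree_acs()] and the
#' wood-density protocol, recovery-period detection per plot
#' ([detect_recovery_start()]), cohort classification from t0 onwards, the
#' five interval fluxes per census interval and their running sums, plot
#' weights proportional to area (normalised to mean 1), and the disturbance
#' intensity covariate.
#'
#' @param inventory long-format inventory as from [read_inventory()] (one row
#'   per tree per census).
#' @param table a `wd_table`; site averages are derived from the inventory
#'   when absent.
#' @param sites data.frame with columns `site_id` and `E`.
#' @param plots data.frame with columns `plot_id`, `site_id`, `area` (ha) and
#'   `logging_time` (decimal years).
#' @param window recovery-detection window after logging, years.
#' @param dbh_min diameter threshold, cm.
#' @param carbon_fraction fraction of biomass that is carbon.
#' @return an object of class `flux_series`: a data.frame with one row per
#'   retained plot and census from t0 on (columns `plot_id`, `site_id`, `t`,
#'   the five interval fluxes, their cumulative versions) with a `meta`
#'   attribute (per-plot area, weight, `t0`, `acs_min`, `acs_prelogging`,
#'   `loss`) and an `excluded` attribute naming dropped plots and reasons.
#' @export
decompose_fluxes <- function(inventory, table, sites, plots, window = 4,
                             dbh_min = 20, carbon_fraction = 0.5) {
  stopifnot(inherits(table, "wd_table"))
  # ensure every site has an average density on file
  for (sid in unique(plots$site_id))
    if (!as.character(sid) %in% names(table$site))
      table <- site_mean_density(
        table, inventory[inventory$site_id == sid, , drop = FALSE], sid)
  inventory <- .inventory_acs(inventory, table, sites, dbh_min, carbon_fraction)

  rows <- list(); meta <- list(); excluded <- list()
  for (p in seq_len(nrow(plots))) {
    pid <- plots$plot_id[p]
    inv_p <- inventory[inventory$plot_id == pid, , drop = FALSE]
    times <- sort(unique(inv_p$census_time))
    acs_t <- vapply(times, function(tt) {
      cen <- inv_p[inv_p$census_time == tt, ]
      sum(cen$acs[cen$status == "alive" & cen$dbh >= dbh_min], na.rm = TRUE)
    }, 0) / plots$area[p]
    pre <- times <= plots$logging_time[p]
    if (!any(pre)) {
      excluded[[as.character(pid)]] <- "no pre-logging census"
      next
    }
    acs_pre <- acs_t[max(which(pre))]
    det <- detect_recovery_start(times, acs_t, plots$logging_time[p], window)
    if (det$excluded) {
      excluded[[as.character(pid)]] <- det$reason
      next
    }
    keep <- times >= det$t0
    tk <- times[keep]
    if (length(tk) < 2) {
      excluded[[as.character(pid)]] <- "fewer than two censuses after t0"
      next
    }
    census_at <- function(tt) inv_p[inv_p$census_time == tt, , drop = FALSE]
    c0 <- census_at(tk[1])
    membership <- stats::setNames(
      rep("survivor", sum(c0$status == "alive" & c0$dbh >= dbh_min)),
      c0$tree_id[c0$status == "alive" & c0$dbh >= dbh_min])
    f <- matrix(0, nrow = length(tk), ncol = 5,
                dimnames = list(NULL, c("Rr", "Rg", "Rl", "Sg", "Sl")))
    prev <- c0
    for (k in 2:length(tk)) {
      curr <- census_at(tk[k])
      coh <- classify_cohorts(prev, curr, membership, dbh_min)
      membership <- coh$membership
      f[k, ] <- interval_fluxes(prev, curr, coh, plots$area[p])
      prev <- curr
    }
    df <- data.frame(plot_id = pid, site_id = plots$site_id[p],
                     t = tk - det$t0, f)
    rows[[as.character(pid)]] <- cumulative_fluxes(df)
    meta[[as.character(pid)]] <- data.frame(
      plot_id = pid, site_id = plots$site_id[p], area = plots$area[p],
      t0 = det$t0, acs_min = det$acs_min, acs_prelogging = acs_pre,
      loss = disturbance_intensity(acs_pre, det$acs_min))
  }
  if (!length(rows)) stop("all plots excluded; no flux series to return")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  meta <- do.call(rbind, meta)
  meta$weight <- meta$area / mean(meta$area)
  rownames(meta) <- NULL
  structure(out, meta = meta,
            excluded = unlist(excluded),
            class = c("flux_series", "data.frame"))
}

#' Per-plot metadata of a flux series
#'
#' @param flux a `flux_series`.
#' @return the per-plot metadata data.frame (area, weight, t0, acs_min,
#'   acs_prelogging, loss).
#' @export
flux_meta <- function(flux) attr(flux, "meta")

#' Write a flux series (and its per-plot metadata) to CSV
#'
#' @param flux a `flux_series`.
#' @param path path of the series CSV; metadata is written next to it with a
#'   `_meta.csv` suffix.
#' @return `path`, invisibly.
#' @export
write_flux_series <- function(flux, path) {
  utils::write.csv(as.data.frame(flux), path, row.names = FALSE)
  utils::write.csv(flux_meta(flux),
                   sub("\\.csv$", "_meta.csv", path), row.names = FALSE)
  invisible(path)
}
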