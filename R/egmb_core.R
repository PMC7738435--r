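#' Reactor operating configuration
#'
#' Describes one well-mixed, semi-continuously operated fermenter: at every
#' exchange event a fixed volume of mixed liquor is discarded and replaced
#' with the same volume of feed sludge. Because the reactor is completely
#' mixed, the fraction of volume discarded equals the fraction of solids
#' discarded, which is what makes SRT = Vc / (exchange_volume /
#' exchange_interval) and lets the discard term of the mass balance collapse
#' to 1/SRT.
#'
#' @param Vc working volume \[mL\].
#' @param exchange_volume volume discarded and replaced per event \[mL\];
#'   must satisfy 0 < exchange_volume <= Vc.
#' @param exchange_interval time between exchange events \[d\].
#' @param Cf feed volatile suspended solids (VSS) concentration \[g/L\].
#' @param Cc reactor VSS concentration \[g/L\] (biomass proxy for the
#'   standing community).
#' @param Cd discarded-stream VSS concentration \[g/L\]; defaults to `Cc`
#'   (well-mixed assumption).
#' @return An object of class `reactor_config` with the given fields plus the
#'   derived volumetric exchange rate `Q = exchange_volume /
#'   exchange_interval` \[mL/d\].
#' @export
reactor_config <- function(Vc, exchange_volume, exchange_interval,
                           Cf = NA_real_, Cc = NA_real_, Cd = Cc) {
  stopifnot(is.numeric(Vc), Vc > 0,
            is.numeric(exchange_volume), exchange_volume > 0,
            exchange_volume <= Vc,
            is.numeric(exchange_interval), exchange_interval > 0)
  for (nm in c("Cf", "Cc", "Cd")) {
    v <- get(nm)
    if (!is.na(v) && v < 0) stop(nm, " must be >= 0")
  }
  structure(list(Vc = Vc, exchange_volume = exchange_volume,
                 exchange_interval = exchange_interval,
                 Q = exchange_volume / exchange_interval,
                 Cf = Cf, Cc = Cc, Cd = Cd),
            class = "reactor_config")
}

#' @export
print.reactor_config <- function(x, ...) {
  cat("Reactor: ", x$Vc, " mL, exchanging ", x$exchange_volume, " mL every ",
      x$exchange_interval, " d (SRT ", format(compute_srt(x)), " d)\n",
      "VSS [g/L]: feed ", x$Cf, ", reactor ", x$Cc, ", discard ", x$Cd, "\n",
      sep = "")
  invisible(x)
}

#' Solids retention time of a semi-continuous schedule
#'
#' SRT = working volume / volumetric exchange rate
#'     = Vc * exchange_interval / exchange_volume.
#'
#' @param cfg a [reactor_config].
#' @return SRT in days.
#' @examples
#' compute_srt(reactor_config(150, 3, 2))   # 100 d
#' compute_srt(reactor_config(150, 32, 0.5))  # 2.34375 d
#' @export
compute_srt <- function(cfg) {
  stopifnot(inherits(cfg, "reactor_config"))
  cfg$Vc * cfg$exchange_interval / cfg$exchange_volume
}

#' Steady-state net growth rate of one taxon
#'
#' The mass balance for taxon x in a well-mixed semi-continuous reactor reads
#' dNx/dt = (feed influx) - (discard outflux) + mu_x * Nx, with influx
#' Qf*Cf*px,f and outflux Qd*Cd*px,d expressed through VSS-scaled relative
#' abundances. At steady state dNx/dt = 0; because the discard stream has the
#' reactor's own composition (Cd = Cc, px,d = px,c) the outflux term reduces
#' to Nx/SRT and the estimator collapses to
#'
#'   mu_x = 1/SRT - (Qf * Cf * px,f) / (Vc * Cc * px,c)   \[1/d\]
#'
#' Unit bookkeeping: both Qf*Cf*p and Vc*Cc*p carry mL * g/L = mg, so the
#' unit factor cancels and mu is in 1/d. A taxon absent from the reactor but
#' present in the feed cannot satisfy the balance at any finite rate: it has
#' been washed out and gets status `washed_out` rather than a sentinel rate.
#'
#' @param p_reactor relative abundance of the taxon in the reactor sample.
#' @param p_feed relative abundance of the taxon in the feed sludge.
#' @param cfg a [reactor_config] with `Cf` and `Cc` set.
#' @param otu_id optional identifier carried through to the record.
#' @return An object of class `growth_rate_record`: list with `otu_id`, `mu`
#'   (\[1/d\], `NA` when undefined), `status` (one of `"estimated"`,
#'   `"washed_out"`, `"absent_everywhere"`), `p_reactor`, `p_feed`.
#' @examples
#' cfg <- reactor_config(150, 3, 2, Cf = 6.2, Cc = 10)
#' compute_growth_rate(0.01, 0, cfg)$mu    # 1/SRT = 0.01 /d, the ceiling
#' compute_growth_rate(0.01, 0.05, cfg)$mu # -0.021 /d, net decay
#' @export
compute_growth_rate <- function(p_reactor, p_feed, cfg, otu_id = NA_character_) {
  stopifnot(inherits(cfg, "reactor_config"),
            p_reactor >= 0, p_reactor <= 1, p_feed >= 0, p_feed <= 1)
  if (p_reactor > 0) {
    if (is.na(cfg$Cc) || cfg$Cc <= 0)
      stop("reactor VSS concentration Cc must be > 0 to estimate a growth rate")
    if (p_feed > 0 && (is.na(cfg$Cf) || cfg$Cf < 0))
      stop("feed VSS concentration Cf must be set for a feed-borne taxon")
    srt <- compute_srt(cfg)
    influx <- if (p_feed > 0) cfg$Q * cfg$Cf * p_feed else 0
    mu <- 1 / srt - influx / (cfg$Vc * cfg$Cc * p_reactor)
    status <- "estimated"
  } else if (p_feed > 0) {
    mu <- NA_real_
    status <- "washed_out"
  } else {
    mu <- NA_real_
    status <- "absent_everywhere"
  }
  structure(list(otu_id = otu_id, mu = mu, status = status,
                 p_reactor = p_reactor, p_feed = p_feed),
            class = "growth_rate_record")
}

#' @export
print.growth_rate_record <- function(x, ...) {
  cat("OTU ", x$otu_id, ": status ", x$status,
      if (x$status == "estimated") paste0(", mu = ", signif(x$mu, 4), " /d"),
      "\n", sep = "")
  invisible(x)
}

#' Growth-rate table for a reactor/feed sample pair
#'
#' Applies the steady-state estimator OTU by OTU over the union of the
#' reactor and feed OTU sets (outer join on OTU id; missing = 0).
#'
#' @param reactor named numeric vector of reactor relative abundances
#'   (names = OTU ids), or a single-column [rel_abundance].
#' @param feed named numeric vector of feed relative abundances, or a
#'   single-column [rel_abundance].
#' @param cfg a [reactor_config] with `Cf` and `Cc` set.
#' @param taxonomy optional named character vector of lineage strings.
#' @return data.frame with columns `otu_id`, `taxonomy`, `p_reactor`,
#'   `p_feed`, `mu`, `status`; estimated rows satisfy `mu <= 1/SRT`.
#' @export
compute_growth_table <- function(reactor, feed, cfg, taxonomy = NULL) {
  as_col <- function(v, what) {
    if (inherits(v, "rel_abundance")) {
      if (ncol(v$p) != 1L)
        stop(what, " must be a single sample column")
      stats::setNames(v$p[, 1L], rownames(v$p))
    } else {
      if (is.null(names(v))) stop(what, " vector must be named by OTU id")
      v
    }
  }
  if (is.null(taxonomy)) {
    for (v in list(reactor, feed))
      if (inherits(v, "rel_abundance")) taxonomy <- c(taxonomy, v$taxonomy)
    if (!is.null(taxonomy)) taxonomy <- taxonomy[!duplicated(names(taxonomy))]
  }
  pr <- as_col(reactor, "reactor")
  pf <- as_col(feed, "feed")
  ids <- union(names(pr), names(pf))
  pr <- ifelse(is.na(pr[ids]), 0, pr[ids])
  pf <- ifelse(is.na(pf[ids]), 0, pf[ids])
  recs <- lapply(seq_along(ids), function(i)
    compute_growth_rate(pr[i], pf[i], cfg, otu_id = ids[i]))
  tax <- if (is.null(taxonomy)) rep("", length(ids)) else {
    tx <- taxonomy[ids]; tx[is.na(tx)] <- ""; unname(tx)
  }
  data.frame(
    otu_id = ids,
    taxonomy = tax,
    p_reactor = unname(pr),
    p_feed = unname(pf),
    mu = vapply(recs, function(r) r$mu, numeric(1L)),
    status = vapply(recs, function(r) r$status, character(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Flag OTUs that violate the steady-state assumption
#'
#' The estimator assumes each taxon's standing abundance stopped changing by
#' the end of the run. This check computes the coefficient of variation (CV,
#' sd/mean) of each OTU's relative abundance across the final sampling days
#' and flags OTUs whose CV exceeds `cv_threshold`. An OTU at zero in every
#' time point has an undefined CV and is treated as stably absent (not
#' flagged).
#'
#' @param x a [rel_abundance] whose columns are the final sampling days
#'   (>= 3 time points).
#' @param cv_threshold flag when CV exceeds this; default 0.3.
#' @return data.frame with columns `otu_id`, `cv`, `flagged`.
#' @export
assess_steady_state <- function(x, cv_threshold = 0.3) {
  stopifnot(inherits(x, "rel_abundance"))
  if (ncol(x$p) < 3L)
    stop("need >= 3 time points to assess steady state, got ", ncol(x$p))
  m <- rowMeans(x$p)
  s <- apply(x$p, 1L, stats::sd)
  cv <- ifelse(m > 0, s / m, NA_real_)
  data.frame(otu_id = rownames(x$p),
             cv = cv,
             flagged = !is.na(cv) & cv > cv_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a growth-rate table as TSV
#'
#' Rates are printed to 4 significant figures in a `mu_per_day` column;
#' any extra columns (steady-state flag, guild) are carried through.
#'
#' @param df a growth-rate data.frame from [compute_growth_table] (optionally
#'   augmented with `steady_state_flag` and/or `guild` columns).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_growth_table <- function(df, path) {
  out <- df
  out$mu_per_day <- signif(out$mu, 4)
  out$mu <- NULL
  lead <- intersect(c("otu_id", "taxonomy", "p_reactor", "p_feed",
                      "mu_per_day", "status"), names(out))
  out <- out[, c(lead, setdiff(names(out), lead)), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a reactor configuration file
#'
#' Plain YAML (or JSON, which YAML subsumes) with the [reactor_config]
#' field names.
#'
#' @param path config file.
#' @return A [reactor_config].
#' @export
read_reactor_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  need <- c("Vc", "exchange_volume", "exchange_interval")
  miss <- setdiff(need, names(y))
  if (length(miss) > 0)
    stop("reactor config is missing field(s): ", paste(miss, collapse = ", "))
  reactor_config(Vc = y$Vc, exchange_volume = y$exchange_volume,
                 exchange_interval = y$exchange_interval,
                 Cf = if (is.null(y$Cf)) NA_real_ else y$Cf,
                 Cc = if (is.null(y$Cc)) NA_real_ else y$Cc,
                 Cd = if (is.null(y$Cd)) {
                   if (is.null(y$Cc)) NA_real_ else y$Cc
                 } else y$Cd)
}

#' @rdname read_reactor_config
#' @param cfg a [reactor_config] to serialize.
#' @export
write_reactor_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "reactor_config"))
  yaml::write_yaml(cfg[c("Vc", "exchange_volume", "exchange_interval",
                         "Cf", "Cc", "Cd")], path)
  invisible(path)
}

#' Packaged reactor presets
#'
#' `expI_control`: 150 mL working volume exchanging 3 mL every 2 d
#' (SRT 100 d), feed VSS 6.2 g/L. `expII_srt_sweep`: four schedules spanning
#' the SRT range 2.34375--37.5 d obtained by varying exchange volume
#' (8--32 mL) and interval (0.5--2 d) at the same working volume.
#'
#' @param preset `"expI_control"` or `"expII_srt_sweep"`.
#' @return For `expI_control`, one [reactor_config]; for `expII_srt_sweep`,
#'   a named list of configs (names `srt<days>`).
#' @export
reactor_preset <- function(preset = c("expI_control", "expII_srt_sweep")) {
  preset <- match.arg(preset)
  if (preset == "expI_control") {
    reactor_config(Vc = 150, exchange_volume = 3, exchange_interval = 2,
                   Cf = 6.2)
  } else {
    sched <- list(c(8, 2), c(12, 1), c(32, 1), c(32, 0.5))
    cfgs <- lapply(sched, function(s)
      reactor_config(Vc = 150, exchange_volume = s[1L],
                     exchange_interval = s[2L], Cf = 6.2))
    names(cfgs) <- vapply(cfgs, function(cf)
      paste0("srt", format(compute_srt(cf))), character(1L))
    cfgs
  }
}
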