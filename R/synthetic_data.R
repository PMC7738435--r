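#' Simulation configuration for a synthetic fermenter community
#'
#' Describes a semi-continuous reactor community with known ground truth:
#' each taxon has a fixed first-order net growth rate `mu_true` inside the
#' reactor, immigrates from the feed sludge in proportion to `feed_profile`,
#' and is diluted by the discard/feed events of `cfg`. Two dynamic modes are
#' available. In `semi_continuous` mode each exchange interval is one cycle:
#' grow (biomass times `exp(mu * interval)`), then discard (all biomass
#' scales by `(Vc - exchange_volume)/Vc`, well-mixed), then feed (add
#' `exchange_volume * Cf * feed_profile` mg). In `continuous_limit` mode the
#' same balance is integrated as a smooth ODE, `dN/dt = mu*N - N/SRT + F`
#' with `F = Q * Cf * feed_profile`, by fixed-step Euler — the regime in
#' which the steady-state estimator is exact.
#'
#' @param mu_true numeric vector of per-taxon net growth rates \[1/d\].
#'   Feed-borne taxa (positive `feed_profile`) must satisfy
#'   `mu_true < 1/SRT`, which guarantees a bounded steady state.
#' @param feed_profile per-taxon fraction of feed biomass; non-negative,
#'   sums to 1 over feed-borne taxa (all-zero allowed for a feed-free run).
#' @param cfg a [reactor_config] with `Cf` set.
#' @param init_biomass per-taxon starting biomass \[mg\]; default `NULL`
#'   starts feed-borne taxa at their analytic steady state (see
#'   [steady_state_biomass]) and resident-only taxa at 0.
#' @param t_end simulated time \[d\]; default 20 SRTs.
#' @param mode `"semi_continuous"` (default) or `"continuous_limit"`.
#' @param euler_dt Euler step \[d\] for the continuous mode (default
#'   `exchange_interval / 50`).
#' @param read_depth reads per sequenced sample (default 1e5).
#' @param vss_noise_cv coefficient of variation of the multiplicative
#'   lognormal noise on VSS measurements (default 0.05).
#' @param seed integer RNG seed for measurement noise and sequencing.
#' @param taxa optional taxon ids (default `taxon01`...).
#' @param taxonomy optional lineage strings.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(mu_true, feed_profile, cfg, init_biomass = NULL,
                       t_end = NULL, mode = c("semi_continuous",
                                              "continuous_limit"),
                       euler_dt = NULL, read_depth = 1e5,
                       vss_noise_cv = 0.05, seed = 1L,
                       taxa = NULL, taxonomy = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "reactor_config"),
            length(mu_true) == length(feed_profile),
            all(feed_profile >= 0), read_depth >= 1, vss_noise_cv >= 0)
  n <- length(mu_true)
  if (is.null(taxa)) taxa <- sprintf("taxon%02d", seq_len(n))
  if (is.null(taxonomy)) taxonomy <- rep("", n)
  stopifnot(length(taxa) == n, length(taxonomy) == n)
  fed <- feed_profile > 0
  if (any(fed)) {
    s <- sum(feed_profile)
    if (abs(s - 1) > 1e-9)
      stop("feed_profile must sum to 1 over feed-borne taxa (got ",
           format(s), ")")
    if (is.na(cfg$Cf) || cfg$Cf <= 0)
      stop("cfg$Cf must be > 0 when any taxon is feed-borne")
  }
  srt <- compute_srt(cfg)
  bad <- which(fed & mu_true >= 1 / srt)
  if (length(bad) > 0)
    stop("feed-borne taxon '", taxa[bad[1L]], "' has mu_true >= 1/SRT (",
         format(1 / srt), "): no bounded steady state")
  if (is.null(t_end)) t_end <- 20 * srt
  if (is.null(euler_dt)) euler_dt <- cfg$exchange_interval / 50
  x <- structure(list(mu_true = mu_true, feed_profile = feed_profile,
                      cfg = cfg, init_biomass = init_biomass, t_end = t_end,
                      mode = mode, euler_dt = euler_dt,
                      read_depth = read_depth, vss_noise_cv = vss_noise_cv,
                      seed = as.integer(seed), taxa = taxa,
                      taxonomy = taxonomy),
                 class = "sim_config")
  # divergence check also covers resident-only taxa seeded with biomass
  init <- init_biomass
  if (!is.null(init)) {
    stopifnot(length(init) == n, all(init >= 0))
    growf <- if (mode == "semi_continuous")
      exp(mu_true * cfg$exchange_interval) *
        (cfg$Vc - cfg$exchange_volume) / cfg$Vc
    else 1 + (mu_true - 1 / srt) * euler_dt
    div <- which(init > 0 & !fed & growf > 1 + 1e-12)
    if (length(div) > 0)
      stop("resident taxon '", taxa[div[1L]],
           "' grows without bound (mu_true exceeds the dilution rate)")
  }
  x
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulated community: ", length(x$mu_true), " taxa, mode ", x$mode,
      ", t_end ", x$t_end, " d, SRT ", format(compute_srt(x$cfg)), " d\n",
      sep = "")
  invisible(x)
}

#' Analytic steady-state biomass
#'
#' For the continuous limit the fixed point of `dN/dt = mu*N - D*N + F` is
#' `N* = F / (D - mu)` with `D = 1/SRT`. For the semi-continuous event map
#' (grow, discard, feed) the post-event fixed point is
#' `N* = f / (1 - exp(mu*tau) * (Vc - v)/Vc)` with per-event feed mass
#' `f = v * Cf * feed_profile`. Resident-only taxa have steady state 0
#' (they wash toward extinction whenever their growth factor per cycle is
#' below 1).
#'
#' @param config a [sim_config].
#' @return numeric vector of per-taxon steady-state biomass \[mg\]; for
#'   `semi_continuous` mode this is the state just after an exchange event.
#' @export
steady_state_biomass <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config$cfg
  srt <- compute_srt(cfg)
  if (config$mode == "continuous_limit") {
    f_rate <- cfg$Q * cfg$Cf * config$feed_profile
    ifelse(config$feed_profile > 0,
           f_rate / (1 / srt - config$mu_true), 0)
  } else {
    tau <- cfg$exchange_interval
    r <- (cfg$Vc - cfg$exchange_volume) / cfg$Vc
    f <- cfg$exchange_volume * cfg$Cf * config$feed_profile
    ifelse(config$feed_profile > 0,
           f / (1 - exp(config$mu_true * tau) * r), 0)
  }
}

#' Run a synthetic reactor community
#'
#' Integrates the community forward (see [sim_config] for the dynamics),
#' records the biomass trajectory, applies multiplicative lognormal noise to
#' the VSS series, and sequences the final reactor state and the feed sludge
#' at finite read depth. In semi-continuous mode the recorded states and the
#' sequenced sample are taken at the sampling moment a bench scientist would
#' use: mixed liquor drawn at the end of a growth phase, just before the
#' discard of the next event. The run is fully reproducible given
#' `config$seed`.
#'
#' @param config a [sim_config].
#' @return An object of class `sim_result`: list with
#'   \describe{
#'     \item{times}{recorded sampling times \[d\].}
#'     \item{biomass}{taxa x time matrix \[mg\] at the recorded times.}
#'     \item{vss_true, vss_meas}{reactor VSS \[g/L\] at the recorded times,
#'       exact and with measurement noise.}
#'     \item{final_counts}{[otu_table] with a `reactor` and a `feed` sample
#'       sequenced at `read_depth`.}
#'     \item{Cc_measured}{noisy VSS at the final sampling time \[g/L\], the
#'       value an analyst would plug into the estimator.}
#'     \item{truth}{data.frame `otu_id`, `mu_true`, `feed_fraction`,
#'       `N_star` (analytic steady state, mg).}
#'     \item{config}{the input configuration.}
#'   }
#' @export
simulate_reactor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config$cfg
  n <- length(config$mu_true)
  set.seed(config$seed)
  init <- config$init_biomass
  if (is.null(init)) init <- steady_state_biomass(config)
  if (config$mode == "semi_continuous") {
    tau <- cfg$exchange_interval
    r <- (cfg$Vc - cfg$exchange_volume) / cfg$Vc
    f <- cfg$exchange_volume * cfg$Cf * config$feed_profile
    if (any(is.na(f))) f <- rep(0, n)  # feed-free run with Cf unset
    n_events <- max(1L, floor(config$t_end / tau + 1e-9))
    grow <- exp(config$mu_true * tau)
    biomass <- matrix(0, n, n_events,
                      dimnames = list(config$taxa, NULL))
    N <- init
    for (k in seq_len(n_events)) {
      N <- N * grow            # growth over one interval
      biomass[, k] <- N        # pre-discard sampling point
      N <- N * r + f           # well-mixed discard, then feed
    }
    times <- tau * seq_len(n_events)
  } else {
    dt <- config$euler_dt
    srt <- compute_srt(cfg)
    f_rate <- cfg$Q * cfg$Cf * config$feed_profile
    if (any(is.na(f_rate))) f_rate <- rep(0, n)
    n_steps <- max(1L, ceiling(config$t_end / dt))
    thin <- max(1L, n_steps %/% 1000L)
    rec <- unique(c(seq(thin, n_steps, by = thin), n_steps))
    biomass <- matrix(0, n, length(rec),
                      dimnames = list(config$taxa, NULL))
    N <- init
    j <- 1L
    for (k in seq_len(n_steps)) {
      N <- N + dt * (config$mu_true * N - N / srt + f_rate)
      N <- pmax(N, 0)
      if (j <= length(rec) && k == rec[j]) {
        biomass[, j] <- N
        j <- j + 1L
      }
    }
    times <- rec * dt
  }
  if (any(biomass < 0) || any(!is.finite(biomass)))
    stop("simulation produced a negative or non-finite biomass")
  vss_true <- colSums(biomass) / cfg$Vc  # mg/mL = g/L
  vss_meas <- vss_true * rlnorm_cv(length(vss_true), config$vss_noise_cv)
  final <- biomass[, ncol(biomass)]
  counts <- cbind(
    reactor = sequence_sample(final, config$read_depth),
    feed = if (any(config$feed_profile > 0))
      sequence_sample(config$feed_profile, config$read_depth)
    else rep(0, n))
  rownames(counts) <- config$taxa
  structure(list(
    times = times, biomass = biomass,
    vss_true = vss_true, vss_meas = vss_meas,
    final_counts = otu_table(counts, config$taxonomy),
    Cc_measured = vss_meas[length(vss_meas)],
    truth = data.frame(otu_id = config$taxa,
                       mu_true = config$mu_true,
                       feed_fraction = config$feed_profile,
                       N_star = steady_state_biomass(config),
                       stringsAsFactors = FALSE),
    config = config), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulated run: ", nrow(x$biomass), " taxa over ",
      format(max(x$times)), " d; final VSS ",
      signif(x$vss_true[length(x$vss_true)], 4), " g/L\n", sep = "")
  invisible(x)
}

# lognormal multiplicative noise with mean 1 and the given CV
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Sequence a sample at finite read depth
#'
#' Multinomial draw of `read_depth` reads with probabilities proportional to
#' biomass, emulating amplicon sequencing of a well-mixed sample.
#'
#' @param biomass non-negative per-taxon biomass (any common unit); total
#'   must be > 0.
#' @param read_depth number of reads to draw.
#' @param seed optional seed for a self-contained reproducible draw; by
#'   default the current RNG stream is used.
#' @return integer vector of read counts summing to `read_depth`, named
#'   like `biomass`.
#' @export
sequence_sample <- function(biomass, read_depth, seed = NULL) {
  stopifnot(all(biomass >= 0), read_depth >= 1)
  if (sum(biomass) <= 0) stop("cannot sequence a sample with zero biomass")
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rmultinom(1L, size = round(read_depth),
                             prob = biomass)[, 1L]
  names(counts) <- names(biomass)
  counts
}

#' Synthetic sludge-fermenter community with guild structure
#'
#' Draws a ground-truth community shaped like a WAS fermenter: a small set
#' of slow-growing syntrophs and methanogens, a larger block of fermenters
#' (all with positive net growth rates drawn between 0.2/SRT and 0.9/SRT),
#' and a block of feed-sludge (WAS) associated decayers with strongly
#' negative rates between -5/SRT and -2/SRT. The decayers carry 70% of the
#' immigrating feed biomass, mirroring feed sludge dominated by upstream
#' aerobic taxa; the rest is spread over the growers.
#'
#' @param cfg a [reactor_config] (its SRT sets the rate scale).
#' @param n_taxa community size (default 30).
#' @param seed RNG seed.
#' @return list with `taxa`, `taxonomy`, `mu_true`, `feed_profile`.
#' @export
example_community <- function(cfg, n_taxa = 30L, seed = 1L) {
  stopifnot(inherits(cfg, "reactor_config"), n_taxa >= 8)
  set.seed(seed)
  srt <- compute_srt(cfg)
  n_syn <- max(2L, round(0.1 * n_taxa))
  n_met <- max(2L, round(0.1 * n_taxa))
  n_was <- round(0.4 * n_taxa)
  n_fer <- n_taxa - n_syn - n_met - n_was
  syn_genera <- c("Syntrophomonas", "Syntrophobacter", "Smithella",
                  "Pelotomaculum", "Syntrophorhabdus")
  met_genera <- c("Methanosaeta", "Methanosarcina", "Methanobacterium",
                  "Methanomassiliicoccus", "Methanolinea")
  fer_genera <- c("Parabacteroides", "Paludibacter", "Microbacter",
                  "Proteiniphilum", "Fervidobacterium", "Treponema")
  was_genera <- c("Terrimonas", "Bryobacter", "Zoogloea", "Haliscomenobacter",
                  "Nitrospira", "Dechloromonas")
  lineage <- function(domain, genus)
    paste(domain, "p__; c__; o__; f__", paste0("g__", genus), sep = "; ")
  taxonomy <- c(
    lineage("Bacteria", rep_len(syn_genera, n_syn)),
    lineage("Archaea", rep_len(met_genera, n_met)),
    lineage("Bacteria", rep_len(fer_genera, n_fer)),
    lineage("Bacteria", rep_len(was_genera, n_was)))
  n_grow <- n_syn + n_met + n_fer
  mu_true <- c(stats::runif(n_grow, 0.2, 0.9) / srt,
               -stats::runif(n_was, 2, 5) / srt)
  w <- c(stats::rgamma(n_grow, shape = 2), stats::rgamma(n_was, shape = 2))
  feed_profile <- c(0.3 * w[seq_len(n_grow)] / sum(w[seq_len(n_grow)]),
                    0.7 * w[-seq_len(n_grow)] / sum(w[-seq_len(n_grow)]))
  list(taxa = sprintf("taxon%02d", seq_len(n_taxa)),
       taxonomy = taxonomy,
       mu_true = mu_true,
       feed_profile = feed_profile)
}

#' Write a self-consistent synthetic fixture to disk
#'
#' Generates a community, runs the simulator, and writes the files the rest
#' of the pipeline consumes: `otu_table.tsv` (reactor duplicates plus a feed
#' sample), `metadata.tsv`, one reactor config YAML per reactor (with `Cc`
#' filled in from the simulated VSS measurement), and one ground-truth TSV
#' per reactor (`taxon`, `mu_true`, `feed_fraction`, `N_star`). All files
#' are plain text in the package's own formats.
#'
#' @param preset `"toy"` (10 taxa, 100-d-SRT schedule, shallow sequencing),
#'   `"expI_control"` (30 taxa, 150 mL / 3 mL / 2 d schedule), or
#'   `"expII_srt_sweep"` (30 taxa run under four schedules spanning SRT
#'   2.34375--37.5 d).
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @return named character vector of the files written, invisibly.
#' @export
make_fixture <- function(preset = c("toy", "expI_control", "expII_srt_sweep"),
                         dir, seed = 1L) {
  preset <- match.arg(preset)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seed <- as.integer(seed)
  if (preset == "expII_srt_sweep") {
    cfgs <- reactor_preset("expII_srt_sweep")
    n_taxa <- 30L
    depth <- 1e5
  } else {
    cfgs <- list(control = reactor_preset("expI_control"))
    n_taxa <- if (preset == "toy") 10L else 30L
    depth <- if (preset == "toy") 5000 else 1e5
  }
  counts <- NULL
  md <- NULL
  files <- character()
  for (i in seq_along(cfgs)) {
    cfg <- cfgs[[i]]
    label <- names(cfgs)[i]
    comm <- example_community(cfg, n_taxa = n_taxa, seed = seed)
    reps <- lapply(1:2, function(rep) {
      sc <- sim_config(comm$mu_true, comm$feed_profile, cfg,
                       t_end = 5 * compute_srt(cfg), read_depth = depth,
                       seed = seed + 97L * i + rep,
                       taxa = comm$taxa, taxonomy = comm$taxonomy)
      simulate_reactor(sc)
    })
    cc <- mean(vapply(reps, function(r) r$Cc_measured, numeric(1L)))
    for (rep in 1:2) {
      sid <- paste0(label, "_R", rep)
      counts <- cbind(counts, reps[[rep]]$final_counts$counts[, "reactor"])
      colnames(counts)[ncol(counts)] <- sid
      md <- rbind(md, data.frame(
        sample_id = sid, role = "reactor",
        day = round(5 * compute_srt(cfg)), replicate_group = label,
        condition = label, stringsAsFactors = FALSE))
    }
    cfg_out <- cfg
    cfg_out$Cc <- cc
    cfg_out$Cd <- cc
    fcfg <- file.path(dir, paste0("config_", label, ".yaml"))
    write_reactor_config(cfg_out, fcfg)
    ftr <- file.path(dir, paste0("truth_", label, ".tsv"))
    utils::write.table(reps[[1L]]$truth, ftr, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, fcfg, ftr)
    if (i == length(cfgs)) {
      counts <- cbind(counts,
                      feed = sequence_sample(comm$feed_profile, depth,
                                             seed = seed + 7L))
      md <- rbind(md, data.frame(
        sample_id = "feed", role = "feed", day = 0,
        replicate_group = "feed", condition = "feed",
        stringsAsFactors = FALSE))
      rownames(counts) <- comm$taxa
      tab <- otu_table(counts, comm$taxonomy)
      fot <- file.path(dir, "otu_table.tsv")
      fmd <- file.path(dir, "metadata.tsv")
      write_otu_table(tab, fot)
      write_sample_metadata(md, fmd)
      files <- c(files, fot, fmd)
    }
  }
  invisible(files)
}
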