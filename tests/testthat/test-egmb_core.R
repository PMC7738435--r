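test_that("SRT follows the exchange schedule", {
  expect_identical(compute_srt(reactor_config(150, 3, 2)), 100)
  expect_identical(compute_srt(reactor_config(150, 8, 2)), 37.5)
  expect_identical(compute_srt(reactor_config(150, 32, 0.5)), 2.34375)
  expect_equal(round(compute_srt(reactor_config(150, 32, 0.5)), 1), 2.3)
  # exchanging the full working volume daily gives SRT 1 d
  expect_identical(compute_srt(reactor_config(75, 75, 1)), 1)
})

test_that("the estimator reproduces hand-computed rates and statuses", {
  cfg <- expI_cfg()
  # no feed input: rate sits at the ceiling 1/SRT
  expect_identical(compute_growth_rate(0.005, 0, cfg)$mu, 0.01)
  # influx balancing standing stock / SRT: mu = 0
  # Q*Cf*pf = Vc*Cc*pr/SRT -> pf = 150*10*0.01/100 / (1.5*6.2)
  pf <- 150 * 10 * 0.01 / 100 / (1.5 * 6.2)
  expect_equal(compute_growth_rate(0.01, pf, cfg)$mu, 0, tolerance = 1e-12)
  # hand arithmetic: 0.01 - (1.5*6.2*0.05)/(150*10*0.01)
  expect_equal(compute_growth_rate(0.01, 0.05, cfg)$mu, -0.021,
               tolerance = 1e-12)
  # statuses
  r <- compute_growth_rate(0, 0.02, cfg)
  expect_identical(r$status, "washed_out")
  expect_true(is.na(r$mu))
  r <- compute_growth_rate(0, 0, cfg)
  expect_identical(r$status, "absent_everywhere")
  expect_true(is.na(r$mu))
  expect_error(compute_growth_rate(0.01, 0.05, reactor_config(150, 3, 2,
                                                              Cf = 6.2)),
               "Cc")
})

test_that("mu is capped at 1/SRT with equality exactly when p_feed = 0", {
  cfg <- expI_cfg()
  srt <- compute_srt(cfg)
  set.seed(5)
  for (i in 1:50) {
    pr <- runif(1, 1e-4, 0.5)
    pf <- sample(c(0, runif(1, 1e-4, 0.5)), 1)
    mu <- compute_growth_rate(pr, pf, cfg)$mu
    expect_lte(mu, 1 / srt)
    if (pf == 0) expect_identical(mu, 1 / srt) else expect_lt(mu, 1 / srt)
  }
})

test_that("mu is monotone in the abundances and biomass-scale invariant", {
  cfg <- expI_cfg()
  mu <- function(pr, pf, cc = 10, cf = 6.2)
    compute_growth_rate(pr, pf, reactor_config(150, 3, 2, Cf = cf,
                                               Cc = cc))$mu
  pf <- seq(0.01, 0.3, length.out = 8)
  expect_true(all(diff(vapply(pf, function(x) mu(0.05, x),
                              numeric(1))) < 0))
  pr <- seq(0.01, 0.3, length.out = 8)
  expect_true(all(diff(vapply(pr, function(x) mu(x, 0.05),
                              numeric(1))) > 0))
  # scaling Cf and Cc together leaves mu unchanged
  expect_equal(mu(0.03, 0.07, cc = 10, cf = 6.2),
               mu(0.03, 0.07, cc = 30, cf = 18.6), tolerance = 1e-12)
})

test_that("estimator is exact on the continuous-culture steady state", {
  # a taxon at N* = F/(D - mu) observed as the whole community: p = 1,
  # Cc = N*/Vc, influx Q*Cf = F; the estimator must return mu identically
  for (D in c(0.05, 0.1, 0.5)) {
    for (mu_true in c(-0.5, -0.1, 0, 0.02)) {
      if (mu_true >= D) next
      for (F_in in c(0.1, 1, 10)) {
        Vc <- 150
        tau <- 1
        v <- Vc * tau * D          # exchange volume giving SRT = 1/D
        Cf <- F_in / (v / tau)
        N_star <- F_in / (D - mu_true)
        cfg <- reactor_config(Vc, v, tau, Cf = Cf, Cc = N_star / Vc)
        expect_equal(compute_growth_rate(1, 1, cfg)$mu, mu_true,
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("growth table outer-joins the OTU universes", {
  cfg <- expI_cfg()
  pr <- c(a = 0.5, b = 0.3, c = 0.2)
  pf <- c(b = 0.4, d = 0.6)
  tab <- compute_growth_table(pr, pf, cfg)
  expect_setequal(tab$otu_id, c("a", "b", "c", "d"))
  # matches element-wise per-OTU calls
  for (i in seq_len(nrow(tab))) {
    ref <- compute_growth_rate(tab$p_reactor[i], tab$p_feed[i], cfg)
    expect_identical(tab$mu[i], ref$mu)
    expect_identical(tab$status[i], ref$status)
  }
  # feed-only OTU is exactly one washed_out record
  expect_identical(tab$status[tab$otu_id == "d"], "washed_out")
  # all-zero feed: every detected OTU sits at 1/SRT
  tab0 <- compute_growth_table(pr, c(a = 0, b = 0, c = 0), cfg)
  expect_true(all(tab0$mu == 1 / compute_srt(cfg)))
})

test_that("steady-state check flags volatile OTUs by CV of abundance", {
  # constant series: CV 0, unflagged
  pc <- rel_from(matrix(rep(c(0.25, 0.75), 4), 2, 4,
                        dimnames = list(c("A", "B"), paste0("d", 1:4))))
  expect_false(any(assess_steady_state(pc)$flagged))
  # doubling series: CV from first principles exceeds 0.3
  pA <- c(0.1, 0.2, 0.4)
  pd <- rel_from(rbind(A = pA, B = 1 - pA))
  res <- assess_steady_state(pd)
  expect_equal(res$cv[res$otu_id == "A"], sd(pA) / mean(pA))
  expect_true(res$flagged[res$otu_id == "A"])
  expect_false(res$flagged[res$otu_id == "B"])
  # all-zero OTU is stable-absent, never flagged
  p0 <- rel_from(rbind(A = c(0, 0, 0), B = c(1, 1, 1)))
  res0 <- assess_steady_state(p0)
  expect_false(res0$flagged[res0$otu_id == "A"])
  expect_true(is.na(res0$cv[res0$otu_id == "A"]))
  expect_error(assess_steady_state(rel_from(cbind(c(1), c(1)))), ">= 3")
})

test_that("reactor config files and growth tables round trip", {
  cfg <- expI_cfg()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_reactor_config(cfg, f)
  back <- read_reactor_config(f)
  expect_equal(back[c("Vc", "exchange_volume", "exchange_interval",
                      "Cf", "Cc", "Cd")],
               cfg[c("Vc", "exchange_volume", "exchange_interval",
                     "Cf", "Cc", "Cd")])
  tab <- compute_growth_table(c(a = 0.6, b = 0.4), c(a = 0.1, b = 0.9), cfg)
  g <- withr::local_tempfile(fileext = ".tsv")
  write_growth_table(tab, g)
  out <- read.delim(g)
  expect_identical(names(out)[1:6],
                   c("otu_id", "taxonomy", "p_reactor", "p_feed",
                     "mu_per_day", "status"))
  expect_equal(out$mu_per_day, signif(tab$mu, 4))
})
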