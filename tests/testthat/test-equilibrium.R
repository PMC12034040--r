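fig_params <- function(dna_tot = 0.5e-6, tetramer = TRUE, Myc_tot = 1e-6) {
  equilibrium_parameters(Myc_tot = Myc_tot, DNAH_tot = dna_tot,
                         DNAL_tot = dna_tot, tetramer = tetramer)
}

test_that("species_from_free satisfies the equilibrium relations exactly", {
  p <- fig_params()
  # no free protein: all DNA free, nothing bound
  sp0 <- species_from_free(0, 0, p)
  expect_equal(sp0$DNAH, p$DNAH_tot)
  expect_equal(sp0$DNAL, p$DNAL_tot)
  expect_true(all(unlist(sp0[c("Myc_DNAH", "Myc_DNAH_2", "Myc_DNAL",
                               "Smad2_DNAH", "Smad2_DNAL")]) == 0))
  # heterodimer-only half-saturation closed form at m = K1
  ph <- fig_params(tetramer = FALSE)
  sph <- species_from_free(ph$K1, 0, ph)
  expect_equal(sph$DNAH, ph$DNAH_tot / 2, tolerance = 1e-12)
  expect_equal(sph$Myc_DNAH, ph$DNAH_tot / 2, tolerance = 1e-12)

  # algebraic oracle: substituting outputs back reproduces every constant
  set.seed(17)
  for (rep in 1:20) {
    m <- 10^runif(1, -9, -5)
    s <- 10^runif(1, -9, -5)
    sp <- species_from_free(m, s, p)
    expect_equal(m * sp$DNAH / sp$Myc_DNAH, p$K1, tolerance = 1e-12)
    expect_equal(sp$Myc_DNAH^2 / sp$Myc_DNAH_2, p$K2, tolerance = 1e-12)
    expect_equal(m * sp$DNAL / sp$Myc_DNAL, p$K_L, tolerance = 1e-12)
    expect_equal(s^2 * sp$DNAH / sp$Smad2_DNAH, p$Ktilde_H, tolerance = 1e-12)
    expect_equal(s^2 * sp$DNAL / sp$Smad2_DNAL, p$Ktilde_L, tolerance = 1e-12)
    # derived tetramer constant K_H = K1^2 K2
    expect_equal(m^2 * sp$DNAH^2 / sp$Myc_DNAH_2, p$K1^2 * p$K2,
                 tolerance = 1e-9)
    # DNA conservation holds by construction
    expect_equal(sp$DNAH + sp$Myc_DNAH + 2 * sp$Myc_DNAH_2 + sp$Smad2_DNAH,
                 p$DNAH_tot, tolerance = 1e-12)
    expect_equal(sp$DNAL + sp$Myc_DNAL + sp$Smad2_DNAL,
                 p$DNAL_tot, tolerance = 1e-12)
  }
})

test_that("equilibrium limits match independent reduced solutions", {
  # Myc_tot = 0: no Myc species; Smad partition solves the 1-D problem
  p0 <- fig_params(Myc_tot = 0)
  st0 <- solve_equilibrium(p0)
  expect_equal(unname(st0$free["Myc"]), 0)
  expect_true(all(st0$bound[c("Myc_DNAH", "Myc_DNAH_2", "Myc_DNAL")] == 0))
  # independent 1-D bisection on the Smad conservation equation
  g <- function(s) {
    h <- p0$DNAH_tot / (1 + s^2 / p0$Ktilde_H)
    l <- p0$DNAL_tot / (1 + s^2 / p0$Ktilde_L)
    s + 2 * s^2 * h / p0$Ktilde_H + 2 * s^2 * l / p0$Ktilde_L - p0$Smad_tot
  }
  lo <- 0; hi <- p0$Smad_tot
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal(unname(st0$free["Smad"]), (lo + hi) / 2,
               tolerance = 1e-9 * p0$Smad_tot)

  # Smad_tot = 0, tetramer off: free Myc is the positive root of the cubic
  # from two-site binding; compare against polyroot
  p1 <- fig_params(tetramer = FALSE)
  p1$Smad_tot <- 0
  st1 <- solve_equilibrium(p1)
  expect_equal(unname(st1$free["Smad"]), 0)
  # m (1 + H/(K1+m) + L/(KL+m)) = Myc_tot, rearranged to a cubic in m
  K1 <- p1$K1; KL <- p1$K_L; H <- p1$DNAH_tot; L <- p1$DNAL_tot
  Mt <- p1$Myc_tot
  # m(K1+m)(KL+m) + H m (KL+m) + L m (K1+m) - Mt (K1+m)(KL+m) = 0
  co <- c(-Mt * K1 * KL,
          K1 * KL + H * KL + L * K1 - Mt * (K1 + KL),
          K1 + KL + H + L - Mt,
          1)
  # scale m = 1e-6 u so polyroot works on O(1) coefficients
  cs <- 1e-6
  co_u <- co * cs^(0:3)
  roots <- cs * polyroot(co_u / max(abs(co_u)))
  real_pos <- Re(roots[abs(Im(roots)) < 1e-9 * max(abs(roots)) &
                         Re(roots) > 0])
  expect_equal(unname(st1$free["Myc"]), min(real_pos),
               tolerance = 1e-9)
})

test_that("solved states satisfy conservation and detailed balance to 1e-9", {
  for (dna in c(0.5e-6, 1e-6)) {
    for (tet in c(TRUE, FALSE)) {
      p <- fig_params(dna_tot = dna, tetramer = tet, Myc_tot = 3e-7)
      st <- solve_equilibrium(p)
      expect_true(all(abs(st$residuals) < 1e-9))
      expect_true(all(c(st$free, st$bound) >= 0))
      m <- st$free[["Myc"]]; s <- st$free[["Smad"]]
      expect_equal(m * st$free[["DNAH"]] / st$bound[["Myc_DNAH"]], p$K1,
                   tolerance = 1e-9)
      expect_equal(s^2 * st$free[["DNAL"]] / st$bound[["Smad2_DNAL"]],
                   p$Ktilde_L, tolerance = 1e-9)
      if (tet) {
        expect_equal(st$bound[["Myc_DNAH"]]^2 / st$bound[["Myc_DNAH_2"]],
                     p$K2, tolerance = 1e-9)
      } else {
        expect_equal(st$bound[["Myc_DNAH_2"]], 0)
      }
    }
  }
})

test_that("solver matches the independent 2-D grid-refinement oracle", {
  for (myc in c(3e-8, 3e-7, 1e-6, 5e-6)) {
    p <- fig_params(Myc_tot = myc)
    st <- solve_equilibrium(p)
    or <- grid_refine_equilibrium(p)
    for (nm in names(st$bound)) {
      expect_equal(unname(st$bound[[nm]]), or[[nm]],
                   tolerance = 1e-6)
    }
    expect_equal(unname(st$free[["Myc"]]), or$Myc, tolerance = 1e-6)
    expect_equal(unname(st$free[["Smad"]]), or$Smad, tolerance = 1e-6)
  }
})

test_that("large-K2 tetramer model converges to the heterodimer-only model", {
  p_on <- fig_params(Myc_tot = 1e-6)
  p_on$K2 <- 1e6
  p_on$K_H <- p_on$K1^2 * p_on$K2
  p_off <- fig_params(Myc_tot = 1e-6, tetramer = FALSE)
  on <- solve_equilibrium(p_on)
  off <- solve_equilibrium(p_off)
  for (nm in c("Myc_DNAH", "Myc_DNAL", "Smad2_DNAH", "Smad2_DNAL")) {
    expect_equal(unname(on$bound[[nm]]), unname(off$bound[[nm]]),
                 tolerance = 1e-4)
  }
  # Myc_tot -> large drives DNAH-bound Smad toward zero
  p_big <- fig_params(Myc_tot = 1e-3)
  st_big <- solve_equilibrium(p_big)
  expect_lt(st_big$bound[["Smad2_DNAH"]],
            solve_equilibrium(fig_params(Myc_tot = 1e-8))$bound[["Smad2_DNAH"]] / 100)
})

test_that("Myc sweep is monotone and sharper with the tetramer, both presets", {
  grid <- 10^seq(-8, -5, length.out = 80)
  for (dna in c(0.5e-6, 1e-6)) {
    sw_on <- sweep_myc_total(fig_params(dna_tot = dna), grid)
    sw_off <- sweep_myc_total(fig_params(dna_tot = dna, tetramer = FALSE),
                              grid)
    tol <- 1e-12 * dna
    expect_true(all(diff(sw_on$states$Myc_DNAH_2) >= -tol))
    expect_true(all(diff(sw_on$states$Smad2_DNAH) <= tol))
    expect_true(all(diff(sw_off$states$Smad2_DNAH) <= tol))
    expect_true(all(sw_on$states$residual_norm < 1e-9))
    expect_gt(sw_on$sharpness[["Smad2_DNAH"]],
              sw_off$sharpness[["Smad2_DNAH"]])
  }
  # a one-point grid leaves sharpness undefined but the state valid
  sw1 <- sweep_myc_total(fig_params(), grid = 1e-6)
  expect_true(is.na(sw1$sharpness[["Smad2_DNAH"]]))
  expect_lt(sw1$states$residual_norm, 1e-9)
})

test_that("cooperativity shows as an effective Hill coefficient above one", {
  grid <- 10^seq(-8, -4.5, length.out = 120)
  sw_on <- sweep_myc_total(fig_params(), grid)
  sw_off <- sweep_myc_total(fig_params(tetramer = FALSE), grid)
  hill <- function(m_free, y) {
    ok <- y > 0 & m_free > 0
    max(diff(log(y[ok])) / diff(log(m_free[ok])))
  }
  expect_gt(hill(sw_on$states$Myc, sw_on$states$Myc_DNAH_2), 1.2)
  expect_lte(hill(sw_off$states$Myc, sw_off$states$Myc_DNAH), 1 + 1e-6)
})

test_that("robustness scan: cooperative sharpening survives K perturbations", {
  grid <- 10^seq(-8, -5, length.out = 40)
  rs <- robustness_scan(fig_params(), factors = c(0.1, 10), grid = grid)
  base <- sweep_myc_total(fig_params(), grid)
  id <- rs[rs$constant == "none", ]
  expect_equal(id$sharpness_on, unname(base$sharpness[["Smad2_DNAH"]]),
               tolerance = 1e-12)
  expect_true(all(rs$cooperative_sharper))
})

test_that("degenerate symmetric parameters treat DNAH and DNAL identically", {
  p <- fig_params(Myc_tot = 0)
  p$Ktilde_L <- p$Ktilde_H   # same Smad affinity for both DNA classes
  st <- solve_equilibrium(p)
  expect_equal(unname(st$free[["DNAH"]]), unname(st$free[["DNAL"]]),
               tolerance = 1e-12)
  expect_equal(unname(st$bound[["Smad2_DNAH"]]),
               unname(st$bound[["Smad2_DNAL"]]), tolerance = 1e-12)
})

test_that("parameter files round-trip with mandatory units", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("Myc_tot: 1 uM", "K1: 145 nM", "K2: 90 nM", "K_L: 500 nM",
               "Ktilde_H: 1e-14 M^2", "Ktilde_L: 2.5e-14 M^2",
               "Smad_tot: 1 uM", "DNAH_tot: 0.5 uM", "DNAL_tot: 0.5 uM",
               "tetramer: yes"), f)
  p <- read_equilibrium_parameters(f)
  expect_equal(p$K1, 145e-9)
  expect_equal(p$Ktilde_L, 2.5e-14)
  expect_equal(p$DNAH_tot, 0.5e-6)
  expect_true(p$tetramer)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("Myc_tot: 1e-6", "K1: 145 nM", "K2: 90 nM", "K_L: 500 nM",
               "Ktilde_H: 1e-14 M^2", "Ktilde_L: 2.5e-14 M^2",
               "Smad_tot: 1 uM", "DNAH_tot: 0.5 uM", "DNAL_tot: 0.5 uM"), bad)
  expect_error(read_equilibrium_parameters(bad), "units")
})
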