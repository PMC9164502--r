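# hand-built 40-record fixture: CG "A" holds 22 clean records; CG "B"
# holds 18 of which 2 have short growth periods, 1 is a growth-rate
# outlier and 1 is a quintuplet, leaving 14 (< 15) so the whole CG drops
gradient_fixture <- function() {
  n <- 40
  df <- data.frame(
    animal_id = sprintf("an%02d", 1:n),
    sire_id = rep(sprintf("s%02d", 1:8), each = 5),
    dam_id = sprintf("d%02d", 1:n),
    cg_id = rep(c("A", "B"), times = c(22, 18)),
    sex = rep(c("F", "M"), 20),
    birth_type = 2L, rear_type = 1L,
    wean_age = 95L, postwean_age = 235L,
    pwgr = rnorm(n, 150, 8), pwwt = rnorm(n, 45, 3),
    genotyped = TRUE, stringsAsFactors = FALSE)
  df$postwean_age[23:24] <- df$wean_age[23:24] + 35   # short period
  df$pwgr[25] <- 150 + 80    # gross growth-rate outlier (> 4 sample SDs)
  df$birth_type[26] <- 5L                             # quintuplet
  df
}

test_that("record filters remove short periods, outliers, quintuplets and small CGs", {
  set.seed(51)
  df <- gradient_fixture()
  out <- filter_for_gradient(df)
  expect_equal(out$report$short_period, 2)
  expect_equal(out$report$pwgr_outlier, 1)
  expect_equal(out$report$quintuplet, 1)
  expect_equal(out$report$small_cg, 14)
  expect_equal(nrow(out$pheno), 22)
  expect_true(all(out$pheno$cg_id == "A"))
  ## idempotence on already-clean data
  again <- filter_for_gradient(out$pheno)
  expect_equal(again$pheno, out$pheno)
  expect_equal(again$report$n_in, again$report$n_out)
})

test_that("CG solutions reduce to group means without genetic variance", {
  set.seed(52)
  df <- data.frame(animal_id = sprintf("a%02d", 1:30),
                   cg_id = rep(c("c1", "c2", "c3"), each = 10),
                   pwgr = rnorm(30, c(120, 150, 180)[rep(1:3, each = 10)], 5),
                   stringsAsFactors = FALSE)
  G <- diag(30); dimnames(G) <- list(df$animal_id, df$animal_id)
  ## fixed variance parameters: no genetic variance, unit residual
  fit <- fit_cg_blue(df, G, fixed = "cg_only", theta = c(0, 1))
  mns <- tapply(df$pwgr, df$cg_id, mean)
  expect_equal(unname(fit$blues["c2"] - fit$blues["c1"]),
               unname(mns["c2"] - mns["c1"]), tolerance = 1e-8)
  expect_equal(unname(fit$blues["c3"] - fit$blues["c1"]),
               unname(mns["c3"] - mns["c1"]), tolerance = 1e-8)
  ## duplicated CGs with identical records get identical solutions
  df2 <- rbind(df, transform(df[df$cg_id == "c2", ],
                             cg_id = "c4",
                             animal_id = sprintf("b%02d", 1:10)))
  G2 <- diag(40); dimnames(G2) <- list(df2$animal_id, df2$animal_id)
  fit2 <- fit_cg_blue(df2, G2, fixed = "cg_only", theta = c(0, 1))
  expect_equal(unname(fit2$blues["c4"]), unname(fit2$blues["c2"]),
               tolerance = 1e-8)
})

test_that("standardisation yields mean zero, unit variance, CG-constant values", {
  blues <- c(g1 = -10, g2 = 10)
  df <- data.frame(animal_id = sprintf("a%02d", 1:40),
                   cg_id = rep(c("g1", "g2"), each = 20),
                   genotyped = TRUE)
  grad <- standardize_gradient(blues, df)
  expect_equal(mean(grad$x), 0, tolerance = 1e-10)
  expect_equal(var(grad$x), 1, tolerance = 1e-10)
  expect_equal(unname(grad$x[1]), -1, tolerance = 0.02)
  expect_true(all(abs(grad$x[1:20] - grad$x[1]) < 1e-12))
  ## re-standardising the produced values changes nothing
  x2 <- (blues[df$cg_id] - grad$mean_used) / grad$sd_used
  expect_equal(unname(x2), unname(grad$x), tolerance = 1e-12)
  ## a single CG cannot be standardised
  expect_error(standardize_gradient(c(g1 = 3), df[df$cg_id == "g1", ]),
               "zero")
})

test_that("gradient SD converts between SD units and g/day", {
  ## 1 SD of the gradient worth 33.674 g/day puts a -2.15 SD group at
  ## -72.4 g/day
  grad <- structure(list(sd_used = 72.4 / 2.15), class = "env_gradient")
  expect_equal(gradient_to_units(grad, -2.15), -72.4, tolerance = 1e-9)
  expect_equal(gradient_to_units(grad, 2.06), 69.4, tolerance = 0.05)
})

test_that("adding a constant to all growth rates leaves the gradient unchanged", {
  set.seed(53)
  df <- data.frame(animal_id = sprintf("a%02d", 1:30),
                   cg_id = rep(c("c1", "c2", "c3"), each = 10),
                   pwgr = rnorm(30, 150, 20), genotyped = TRUE,
                   stringsAsFactors = FALSE)
  G <- diag(30); dimnames(G) <- list(df$animal_id, df$animal_id)
  f1 <- fit_cg_blue(df, G, fixed = "cg_only", theta = c(0.5, 1))
  df2 <- transform(df, pwgr = pwgr + 100)
  f2 <- fit_cg_blue(df2, G, fixed = "cg_only", theta = c(0.5, 1))
  g1 <- standardize_gradient(f1, df)
  g2 <- standardize_gradient(f2, df2)
  expect_equal(g1$x, g2$x, tolerance = 1e-8)
})

test_that("CG effects are recovered from simulated growth-rate records", {
  pop <- small_population(seed = 54, n = 2000, m = 1000, n_cg = 40,
                          n_sires = 100)
  flt <- filter_for_gradient(pop$sim$pheno)
  blue <- fit_cg_blue(flt$pheno, pop$grm)
  truth <- pop$sim$truth$cg_true[names(blue$blues)]
  expect_gt(cor(blue$blues, truth), 0.9)
  expect_gt(cor(blue$blues, truth, method = "spearman"), 0.85)
  ## and the standardised gradient tracks the true environment
  grad <- standardize_gradient(blue, flt$pheno)
  common <- intersect(names(grad$x), pop$sim$pheno$animal_id)
  xt <- pop$sim$truth$x_true[match(common, pop$sim$pheno$animal_id)]
  expect_gt(cor(grad$x[common], xt), 0.9)
})

test_that("reaction-norm filters apply the weight rule and the CG-or-half-sib rule", {
  set.seed(55)
  n <- 60
  df <- data.frame(
    animal_id = sprintf("a%02d", 1:n),
    sire_id = c(rep(sprintf("s%02d", 1:28), each = 2), "s90", "s91",
                "s92", "s93"),
    dam_id = sprintf("d%02d", 1:n),
    cg_id = c(rep("big", 56), "tiny1", "tiny1", "tiny2", "tiny3"),
    pwwt = rnorm(n, 45, 1), genotyped = TRUE, stringsAsFactors = FALSE)
  ## the half-sib pair in the tiny CG shares a sire; the two singletons
  ## share nothing
  df$sire_id[57:58] <- "s50"
  df$pwwt[1:3] <- 45 + 50       # gross outliers in the big CG
  out <- filter_for_rnm(df, NULL)
  expect_equal(out$report$pwwt_outlier, 3)
  expect_equal(out$report$no_cg_or_halfsib, 2)
  expect_equal(nrow(out$pheno), 55)
  expect_true(all(c("a57", "a58") %in% out$pheno$animal_id))  # kept: half-sibs
  expect_false(any(c("a59", "a60") %in% out$pheno$animal_id))
})

test_that("the pedigree relationship matrix reproduces textbook kinships", {
  A <- nrm_from_pedigree(c("p1", "p2", "p3"),
                         c("S", "S", "S"),
                         c("D1", "D1", "D2"))
  expect_equal(A["p1", "p2"], 0.5)    # full sibs
  expect_equal(A["p1", "p3"], 0.25)   # paternal half sibs
  expect_equal(A["p1", "p1"], 1)      # non-inbred
  expect_equal(A["p1", "S"], 0.5)     # parent-offspring
  expect_true(isSymmetric(A))
  ## an inbred animal: sire mated to his own daughter
  B <- nrm_from_pedigree(c("d", "x"), c("S", "S"), c(NA, "d"))
  expect_equal(B["x", "x"], 1.25)
})

test_that("pedigree and genomic relationships agree for the CG model at small scale", {
  pop <- small_population(seed = 56, n = 300, m = 2000, n_cg = 10,
                          n_sires = 20)
  ped <- pop$sim$panel$pedigree
  A <- nrm_from_pedigree(ped$animal_id, ped$sire_id,
                         rep(NA_character_, nrow(ped)))[ped$animal_id,
                                                        ped$animal_id]
  flt <- filter_for_gradient(pop$sim$pheno, min_cg = 10)
  b_g <- fit_cg_blue(flt$pheno, pop$grm)
  b_a <- fit_cg_blue(flt$pheno, A)
  expect_gt(cor(b_g$blues, b_a$blues), 0.98)
})
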