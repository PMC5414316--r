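test_that("worked-example leverages match under both parameterisations", {
  fit_m <- gblup(table1_genotypes(), table1_phenotypes(), lambda = 10,
                 model = "mem")
  fit_b <- gblup(table1_genotypes(), table1_phenotypes(), lambda = 10,
                 model = "bvm")
  h <- leverage(fit_m)
  cc <- leverage(fit_b)
  expect_equal(attr(h, "source"), "MEM-H")
  expect_equal(attr(cc, "source"), "BVM-C")
  expect_equal(as.vector(round(h, 2)), c(0.46, 0.51, 0.55))
  expect_equal(as.vector(round(cc, 2)), c(0.46, 0.51, 0.55))
  expect_equal(as.vector(h), as.vector(cc), tolerance = 1e-8)
})

test_that("leverages match an explicitly formed hat matrix", {
  set.seed(21)
  inst <- rand_instance(6, 4)
  fit <- gblup(inst$g, inst$y, lambda = 2, model = "mem")
  Xs <- cbind(1, inst$g)
  H <- Xs %*% solve(crossprod(Xs) + diag(c(0, rep(2, 4)))) %*% t(Xs)
  expect_equal(as.vector(leverage(fit)), unname(diag(H)), tolerance = 1e-9)
})

test_that("closed-form LOOCV residuals equal the naive refitting oracle", {
  fit <- gblup(table1_genotypes(), table1_phenotypes(), lambda = 10,
               model = "mem")
  cv <- loocv(fit, strategy = "mem")
  nv <- loocv(fit, strategy = "naive")
  expect_equal(unname(round(cv$residuals, 2)), c(1.13, 1.21, -2.66))
  expect_equal(unname(cv$residuals), unname(nv$residuals),
               tolerance = 1e-8)

  # identical dosage rows with a shared phenotype: every record predicts
  # the others, residuals all equal, and the naive oracle agrees
  g <- genotype_matrix(matrix(rep(c(1, 2, 0), each = 4), 4, 3))
  yc <- rep(1.5, 4)
  f2 <- gblup(g, yc, lambda = 1, model = "mem")
  expect_warning(cv2 <- loocv(f2, strategy = "mem"), "constant")
  expect_equal(diff(range(cv2$residuals)), 0, tolerance = 1e-10)
  expect_warning(nv2 <- loocv(f2, strategy = "naive"), "constant")
  expect_equal(unname(cv2$residuals), unname(nv2$residuals),
               tolerance = 1e-8)
})

test_that("BVM strategy I agrees with MEM strategy and the oracle", {
  fit_b <- gblup(table1_genotypes(), table1_phenotypes(), lambda = 10,
                 model = "bvm")
  cv1 <- loocv(fit_b, strategy = "bvm1")
  expect_equal(unname(round(cv1$residuals, 2)), c(1.13, 1.21, -2.66))
  set.seed(31)
  for (k in 1:10) {
    inst <- rand_instance(sample(3:5, 1), sample(7:12, 1))
    fit <- tryCatch(gblup(inst$g, inst$y, lambda = 5, model = "bvm"),
                    error = function(e) NULL)   # rank-deficient XX'
    if (is.null(fit)) next
    e1 <- loocv(fit, strategy = "bvm1")$residuals
    em <- loocv(fit, strategy = "mem")$residuals
    en <- loocv(fit, strategy = "naive")$residuals
    expect_equal(unname(e1), unname(em), tolerance = 1e-8)
    expect_equal(unname(e1), unname(en), tolerance = 1e-8)
  }
})

test_that("Q matrix reproduces the worked-example augmented covariance", {
  qm <- build_q(table1_genotypes(), table1_phenotypes(), table1_vc())
  expect_equal(qm$sigma2_L_used, 1000)
  V <- qm$q[-1, -1]
  expect_equal(round(diag(V), 2), c(1002.40, 1001.70, 1001.90))
  expect_equal(round(V[upper.tri(V)], 2), c(1000.80, 1000.80, 1000.30))
  # border is exactly y; matrix exactly symmetric; inverse is an inverse
  expect_identical(qm$q[1, -1], unname(table1_phenotypes()))
  expect_identical(qm$q, t(qm$q))
  expect_equal(qm$q_inv %*% qm$q, diag(4), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("strategy II recovers the worked-example residuals and PEV", {
  qm <- build_q(table1_genotypes(), table1_phenotypes(), table1_vc())
  cv <- loocv(qm)
  # BLP with a random mean at sigma2_L = 1000: close to, not identical to,
  # the fixed-mean answer (1.13, 1.21, -2.66)
  expect_lt(max(abs(cv$residuals - c(1.13, 1.21, -2.66))), 1e-2)
  expect_false(is.null(cv$pev))
  expect_true(all(cv$reliability > 0 & cv$reliability < 1))
  # the same numbers through the fit-level interface
  fit <- gblup(table1_genotypes(), table1_phenotypes(), vc = table1_vc())
  cv2 <- loocv(fit, strategy = "bvm2")
  expect_equal(cv$residuals, cv2$residuals, tolerance = 1e-12)
})

test_that("strategy II converges to strategy I as sigma2_L grows", {
  set.seed(41)
  inst <- rand_instance(5, 9)
  fit <- gblup(inst$g, inst$y, lambda = 10)
  e1 <- loocv(fit, strategy = "bvm1")$residuals
  gaps <- vapply(c(1e3, 1e5, 1e7), function(sL) {
    e2 <- loocv(fit, strategy = "bvm2", sigma2_L = sL)$residuals
    max(abs(e2 - e1))
  }, 0)
  expect_true(all(diff(gaps) <= 1e-10))
  expect_lt(gaps[1], 1e-3 * max(abs(e1)))
  expect_lt(gaps[3], 1e-6 * max(abs(e1)))
})

test_that("PEV depends on the covariance structure, not the phenotypes", {
  set.seed(51)
  inst <- rand_instance(6, 10)
  vc <- variance_components(sigma2_beta = 0.2, sigma2_e = 1)
  p1 <- loocv(build_q(inst$g, inst$y, vc))$pev
  p2 <- loocv(build_q(inst$g, inst$y + 3, vc))$pev
  p3 <- loocv(build_q(inst$g, stats::rnorm(6), vc))$pev
  expect_equal(p1, p2, tolerance = 1e-8)
  expect_equal(p1, p3, tolerance = 1e-8)
})

test_that("reliability decreases in the residual variance", {
  set.seed(61)
  inst <- rand_instance(7, 12)
  r <- lapply(c(1, 2, 4), function(se2)
    loocv(build_q(inst$g, inst$y,
                  variance_components(sigma2_beta = 0.2, sigma2_e = se2,
                                      sigma2_L = 1000)))$reliability)
  expect_true(all(r[[1]] > r[[2]]))
  expect_true(all(r[[2]] > r[[3]]))
  for (rel in r) expect_true(all(rel > 0 & rel < 1))
})

test_that("predictions plus residuals reproduce observations exactly", {
  fit <- gblup(table1_genotypes(), table1_phenotypes(), lambda = 10)
  for (s in c("mem", "bvm1", "bvm2", "naive")) {
    cv <- loocv(fit, strategy = s)
    expect_identical(cv$predictions, cv$y - cv$residuals)
    expect_equal(cv$predictions + cv$residuals, cv$y)
  }
})

test_that("PRESS and accuracy aggregate correctly over subgroups", {
  fit <- gblup(table1_genotypes(), table1_phenotypes(), lambda = 10)
  cv <- loocv(fit)
  expect_identical(cv$press, sum(cv$residuals^2))
  # arithmetic on the printed two-decimal residuals
  expect_equal(sum(round(cv$residuals, 2)^2),
               1.13^2 + 1.21^2 + 2.66^2)
  expect_equal(cv$accuracy,
               stats::cor(cv$y, cv$predictions))
  # subgroup PRESS is additive over a partition
  s12 <- loo_summary(cv, subset = c("1", "2"))
  s3 <- sum(cv$residuals["3"]^2)
  expect_equal(s12$press + s3, cv$press)
  # degenerate subgroups
  expect_error(loo_summary(cv, subset = "1"), "fewer than 2")
  expect_error(loo_summary(cv, subset = c("1", "9")), "not found")
  # perfect pair
  cv_fake <- cv
  cv_fake$predictions <- cv_fake$y
  expect_equal(loo_summary(cv_fake, subset = c("1", "2"))$accuracy, 1)
})

test_that("naive LOOCV can refit a spot-check subset only", {
  set.seed(71)
  inst <- rand_instance(12, 4)
  fit <- gblup(inst$g, inst$y, lambda = 3)
  nv <- loocv(fit, strategy = "naive", refit = c(2, 5, 9))
  expect_identical(unname(which(!is.na(nv$residuals))), c(2L, 5L, 9L))
  full <- loocv(fit, strategy = "mem")
  expect_equal(unname(nv$residuals[c(2, 5, 9)]),
               unname(full$residuals[c(2, 5, 9)]), tolerance = 1e-8)
  expect_identical(nv$subset, c(2L, 5L, 9L))
})

test_that("minimal two-record case predicts each record from the other", {
  g <- genotype_matrix(rbind(c(0, 1), c(2, 1)))
  y <- c(1, -1)
  fit <- gblup(g, y, lambda = 4, model = "mem")
  nv <- loocv(fit, strategy = "naive")
  # leaving out record j, the training set is the single other record
  for (j in 1:2) {
    other <- 3 - j
    b <- ref_mem_solution(g[other, , drop = FALSE], y[other], 4)
    expect_equal(unname(nv$residuals[j]),
                 y[j] - drop(c(1, g[j, ]) %*% b), tolerance = 1e-10)
  }
  h <- leverage(fit)
  expect_true(all(h > 0 & h < 1))
})

test_that("degenerate leverage and Q singularity raise hard errors", {
  # lambda ~ 0 with an interpolating design drives leverage to 1
  g <- genotype_matrix(rbind(c(0, 1), c(2, 1), c(1, 0)))
  fit <- gblup(g, c(1, 2, 3), lambda = 1e-14, model = "mem")
  expect_error(leverage(fit), "degenerate leverage")
  expect_error(loocv(fit, strategy = "mem"), "degenerate leverage")
})

test_that("loocv result methods print, tabulate and plot", {
  fit <- gblup(table1_genotypes(), table1_phenotypes(), vc = table1_vc())
  cv <- loocv(fit, strategy = "bvm2")
  expect_output(print(cv), "PRESS")
  d <- as.data.frame(cv)
  expect_identical(names(d), c("id", "y", "y_hat", "e_hat", "leverage",
                               "pev", "reliability"))
  expect_true(all(is.na(d$leverage)))
  expect_false(anyNA(d$pev))
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(cv))
})
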