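test_that("minimum group distance matches an exhaustive pair scan", {
  set.seed(22)
  x <- matrix(rnorm(30), 10, 3)
  ia <- 1:4; ib <- 5:10
  brute <- min(apply(expand.grid(ia, ib), 1, function(p)
    sqrt(sum((x[p[1], ] - x[p[2], ])^2))))
  expect_equal(min_group_distance(x, ia, ib), brute, tolerance = 1e-12)

  y <- rbind(c(0, 0, 0), c(0.2, 0, 0))
  expect_equal(min_group_distance(y, 1, 2), 0.2)
  expect_equal(min_group_distance(rbind(y, y), 1:2, 3:4), 0)
})

test_that("salt-bridge occupancy recovers planted fractions", {
  top <- reg_top_np()
  pl <- plant_contact_ensemble(top, list(c("K373", "D391"),
                                         c("R379", "D393")),
                               c(0.25, 0.5), n_frames = 400)
  occ <- saltbridge_occupancy(pl, top)
  expect_equal(occ["K373", "D391"], 0.25)
  expect_equal(occ["R379", "D393"], 0.5)
  expect_equal(occ["D391", "K373"], 0.25)  # symmetric
  # same-sign pairs are not scored
  expect_true(is.na(occ["K373", "R379"]))
  expect_true(all(is.na(diag(occ))))
  # mean over the planted pairs matches the plan
  expect_equal(mean(c(occ["K373", "D391"], occ["R379", "D393"])), 0.375)
})

test_that("occupancies are monotone in the cutoff and bounded", {
  top <- reg_top_np()
  pl <- plant_contact_ensemble(top, c("K373", "D391"), 0.3,
                               n_frames = 100)
  o1 <- saltbridge_occupancy(pl, top, cutoff = 0.2)
  o2 <- saltbridge_occupancy(pl, top, cutoff = 0.35)
  o3 <- saltbridge_occupancy(pl, top, cutoff = 1.0)
  v <- function(o) o["K373", "D391"]
  expect_lte(v(o1), v(o2))
  expect_lte(v(o2), v(o3))
  vals <- o2[!is.na(o2)]
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("hbond occupancy with identical groups matches the salt-bridge path", {
  top <- reg_top_np()
  pl <- plant_contact_ensemble(top, c("K373", "D391"), 0.4,
                               n_frames = 100, cutoff = 0.30)
  g <- charged_groups(top)
  sb <- saltbridge_occupancy(pl, top, cutoff = 0.30)
  hb <- hbond_occupancy(pl, g, g, cutoff = 0.30)
  expect_equal(hb["K373", "D391"], sb["K373", "D391"])
  expect_equal(hb["K373", "D391"], 0.4)
})

test_that("occupancy differences are exact and antisymmetric", {
  top <- reg_top_np()
  a <- plant_contact_ensemble(top, c("K373", "D391"), 0.62,
                              n_frames = 100)
  b <- plant_contact_ensemble(top, c("K373", "D391"), 0.50,
                              n_frames = 100)
  oa <- saltbridge_occupancy(a, top)
  ob <- saltbridge_occupancy(b, top)
  d <- occupancy_difference(oa, ob)
  expect_equal(d["K373", "D391"], 0.12)
  expect_equal(occupancy_difference(ob, oa)["K373", "D391"], -0.12)
  z <- occupancy_difference(oa, oa)
  expect_true(all(z[!is.na(z)] == 0))
})

test_that("phospho pairs align by author number across phospho conditions", {
  fp <- reg_top_fp()
  a <- plant_contact_ensemble(fp, c("R379", "pS376"), 0.8, n_frames = 50)
  b <- plant_contact_ensemble(fp, c("R379", "pS376"), 0.2, n_frames = 50)
  d <- occupancy_difference(saltbridge_occupancy(a, fp),
                            saltbridge_occupancy(b, fp))
  expect_true("S376" %in% rownames(d))  # matched by residue number
  expect_equal(d["R379", "S376"], 0.6)
  # pairs charged in only one condition are dropped from the difference
  np <- reg_top_np()
  c0 <- plant_contact_ensemble(np, c("K373", "D391"), 0.1, n_frames = 50)
  d2 <- occupancy_difference(saltbridge_occupancy(a, fp),
                             saltbridge_occupancy(c0, np))
  expect_false("S376" %in% rownames(d2))
  expect_true("K373" %in% rownames(d2))
})

test_that("contact masks agree with occupancy bookkeeping", {
  top <- reg_top_np()
  pl <- plant_contact_ensemble(top, c("K373", "D391"), 0.25,
                               n_frames = 1000)
  mask <- contact_mask(pl, top, c("K373", "D391"))
  expect_equal(sum(mask), 250L)
  occ <- saltbridge_occupancy(pl, top)
  expect_equal(mean(mask), occ["K373", "D391"])

  far <- plant_contact_ensemble(top, c("K373", "D391"), 0, n_frames = 20)
  expect_false(any(contact_mask(far, top, c("K373", "D391"))))
})

test_that("mean reductions and top-change listings are consistent", {
  top <- reg_top_np()
  pl <- plant_contact_ensemble(top, list(c("K373", "D391"),
                                         c("R379", "D393")),
                               c(0.2, 0.6), n_frames = 100)
  occ <- saltbridge_occupancy(pl, top)
  m <- occupancy_mean(occ)
  expect_gte(m["mean_observed_pairs"], m["mean_all_pairs"])

  base <- plant_contact_ensemble(top, c("K373", "D391"), 0,
                                 n_frames = 100)
  d <- occupancy_difference(occ, saltbridge_occupancy(base, top))
  tk <- top_occupancy_changes(d, k = 2)
  expect_equal(nrow(tk), 2L)
  expect_gte(abs(tk$delta[1]), abs(tk$delta[2]))
})
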