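test_that("mass-univariate t-values match a per-voxel lm() oracle to 1e-8", {
  set.seed(10)
  d <- c(8, 9, 8)
  n <- 14
  group <- factor(rep(c("control", "carrier"), each = 7),
                  levels = c("control", "carrier"))
  ages <- runif(n, 30, 65)
  imgs <- lapply(seq_len(n), function(i) {
    new_volume(array(rnorm(prod(d), mean = 10), d), 3)
  })
  mask <- new_volume(array(TRUE, d), 3)
  des <- make_design(group, ages, direction = "hypo")
  fit <- fit_glm(imgs, des, mask)
  expect_equal(fit$df, n - 3)

  vox <- sample(prod(d), 100)
  g <- as.numeric(group == "carrier")
  for (v in vox) {
    y <- sapply(imgs, function(im) im[v])
    lmfit <- lm(y ~ g + I(ages - mean(ages)))
    tv <- summary(lmfit)$coefficients["g", "t value"]
    # contrast is control - carrier: sign flips
    expect_equal(fit$tmap[v], -tv, tolerance = 1e-8)
  }
})

test_that("degenerate designs and contrasts are rejected", {
  d <- c(6, 6, 6)
  imgs <- lapply(1:8, function(i) new_volume(array(rnorm(216), d), 3))
  mask <- new_volume(array(TRUE, d), 3)
  group <- factor(rep(c("control", "carrier"), each = 4),
                  levels = c("control", "carrier"))
  des <- make_design(group)
  des$contrast[] <- 0
  expect_error(fit_glm(imgs, des, mask), "zeros")
  des2 <- make_design(group)
  des2$X <- cbind(des2$X, dup = des2$X[, "carrier"])
  des2$contrast <- c(des2$contrast, 0)
  expect_error(fit_glm(imgs, des2, mask), "rank deficient")
  g4 <- group[c(1, 2, 5, 6)]
  expect_error(fit_glm(imgs[1:4], make_design(g4, age = c(30, 40, 50, 60)),
                       mask),
               "more subjects")
  expect_error(make_design(c("a", "b")), "control")
})

test_that("height thresholding uses the upper-tail t quantile", {
  d <- c(6, 6, 6)
  tm <- new_volume(array(0, d), 3)
  tm[1, 1, 1] <- 3.4
  tm[2, 1, 1] <- 3.2
  out <- height_threshold(tm, df = 40, p = 0.001)
  expect_equal(attr(out, "critical_t"), 3.307, tolerance = 1e-3)
  expect_true(out[1, 1, 1])
  expect_false(out[2, 1, 1])
  # all-zero map -> empty
  expect_equal(sum(height_threshold(new_volume(array(0, d), 3), 40)), 0)
  # p = .5 keeps about half of a symmetric noise map
  set.seed(11)
  noise <- new_volume(array(rt(20000, df = 40), c(20, 25, 40)), 3)
  frac <- mean(unclass(height_threshold(noise, 40, p = 0.5)))
  expect_equal(frac, 0.5, tolerance = 0.02)
  expect_error(height_threshold(tm, 40, p = 0.7), "0.5")
})

test_that("clusterize finds 18-connected components and applies the extent filter", {
  d <- c(12, 12, 12)
  b <- array(FALSE, d)
  b[2:11, 2:11, 2] <- TRUE            # plate of 100
  b[2:11, 2:11, 5:6] <- TRUE          # slab of 200
  tab <- clusterize(new_volume(b, 3), extent = 150)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$size, 200L)
  # both survive at extent 1, sorted by size
  tab2 <- clusterize(new_volume(b, 3), extent = 1)
  expect_equal(tab2$size, c(200L, 100L))
  # empty input and single voxel
  expect_equal(nrow(clusterize(new_volume(array(FALSE, d), 3))), 0)
  s <- array(FALSE, d); s[3, 3, 3] <- TRUE
  expect_equal(clusterize(new_volume(s, 3), extent = 1)$size, 1L)
  # edge-sharing voxels are one cluster under 18- but not 6-connectivity
  e <- array(FALSE, d); e[3, 3, 3] <- TRUE; e[4, 4, 3] <- TRUE
  expect_equal(nrow(clusterize(new_volume(e, 3), 18, extent = 1)), 1)
  expect_equal(nrow(clusterize(new_volume(e, 3), 6, extent = 1)), 2)
})

test_that("clusterize agrees with an igraph flood-fill oracle on random volumes", {
  skip_if_not_installed("igraph")
  set.seed(12)
  offs <- petnorm:::conn_offsets(18)
  for (rep in 1:5) {
    d <- c(10, 10, 10)
    b <- array(runif(prod(d)) < 0.2, d)
    tab <- clusterize(new_volume(b, 3), extent = 1)
    idx <- which(b)
    if (!length(idx)) next
    co <- arrayInd(idx, d)
    edges <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k) {
      nb <- sweep(co, 2, offs[k, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      lin <- nb[ok, 1] + (nb[ok, 2] - 1) * d[1] + (nb[ok, 3] - 1) * d[1] * d[2]
      tgt <- match(lin, idx)
      src <- which(ok)[!is.na(tgt)]
      cbind(src, tgt[!is.na(tgt)])
    }))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
    sizes <- sort(as.integer(table(igraph::components(g)$membership)))
    expect_equal(sort(tab$size), sizes)
  }
})

test_that("percent difference is plain arithmetic on group means", {
  d <- c(5, 5, 5)
  imgs <- c(lapply(1:3, function(i) new_volume(array(1, d), 3)),
            lapply(1:3, function(i) new_volume(array(0.8, d), 3)))
  groups <- rep(c("control", "carrier"), each = 3)
  expect_equal(percent_difference(imgs, groups, 1:10), 20, tolerance = 1e-12)
  imgs2 <- c(imgs[1:3], imgs[1:3])
  expect_equal(percent_difference(imgs2, groups, 1:10), 0, tolerance = 1e-12)
  zero <- lapply(1:6, function(i) new_volume(array(0, d), 3))
  expect_error(percent_difference(zero, groups, 1:10), "zero")
  expect_error(percent_difference(imgs, groups, integer(0)), "empty")
})

test_that("identical images yield an empty cluster table", {
  d <- c(10, 12, 10)
  img <- new_volume(array(5, d), 3)
  imgs <- lapply(1:12, function(i) img)
  group <- factor(rep(c("control", "carrier"), each = 6),
                  levels = c("control", "carrier"))
  mask <- new_volume(array(TRUE, d), 3)
  cf <- suppressWarnings(cluster_fwe(imgs, make_design(group), mask,
                                     n_perm = 99, seed = 1, extent = 1))
  expect_equal(nrow(cf$table), 0)
  expect_error(cluster_fwe(imgs, make_design(group), mask, n_perm = 99),
               "seed")
})

test_that("an injected lesion is recovered inside a flagged cluster at low noise", {
  spec <- phantom_spec(grid_dims = c(24, 28, 24), n_controls = 10,
                       n_carriers = 8, noise_sd = 2,
                       lesion_defs = tibble::tibble(region = "thalamus_l",
                                                    effect = -0.25),
                       atrophy_defs = tibble::tibble(), seed = 31L)
  tpl <- build_template(spec)
  co <- simulate_cohort(spec, tpl)
  mask <- make_analysis_mask(tpl$gm_prob, tpl)
  norm <- lapply(co$uptake, proportional_normalize, mask = mask)
  sm <- lapply(norm, smooth_volume, fwhm_mm = 8, mask = mask)
  region <- which(unclass(region_mask(tpl, "thalamus_l")) &
                    unclass(mask$mask))
  cf <- suppressWarnings(cluster_fwe(
    sm, make_design(co$participants$group, co$participants$age), mask,
    n_perm = 199, seed = 77, extent = floor(length(region) / 2),
    pd_images = norm))
  expect_gte(nrow(cf$table), 1)
  expect_true(any(cf$table$significant))
  lm_ <- unclass(attr_label_map <- cf$label_map)
  sig_ids <- cf$table$cluster_id[cf$table$significant]
  expect_gte(mean(lm_[region] %in% sig_ids), 0.9)
})

test_that("the group-by-age slope interaction is null-calibrated and powered", {
  d <- c(6, 6, 6)
  n <- 24
  group <- rep(c("control", "carrier"), each = 12)
  mask <- new_volume(array(TRUE, d), 3)
  set.seed(14)
  ages <- c(runif(12, 30, 65), runif(12, 30, 65))
  # equal slopes: average interaction t near zero
  imgs <- lapply(seq_len(n), function(i) {
    new_volume(array(100 - 0.5 * ages[i] + rnorm(prod(d)), d), 3)
  })
  fit <- slope_interaction_test(imgs, ages, group, mask)
  expect_lt(abs(mean(unclass(fit$tmap), na.rm = TRUE)), 0.2)
  # strongly different slopes: detected
  g <- as.numeric(group == "carrier")
  imgs2 <- lapply(seq_len(n), function(i) {
    sl <- -0.5 + 3 * g[i]
    new_volume(array(100 + sl * ages[i] + rnorm(prod(d), 0, 0.5), d), 3)
  })
  fit2 <- slope_interaction_test(imgs2, ages, group, mask)
  expect_gt(min(unclass(fit2$tmap), na.rm = TRUE), 5)
  expect_error(slope_interaction_test(imgs, rep(50, n), group, mask),
               "degenerate")
})
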