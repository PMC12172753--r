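test_that("interpolation reproduces amplitudes at stimulation vertices", {
  m <- make_flat_patch_mesh(9, 9, 2)
  center <- project_event_to_vertex(c(0, 0, 0), m)
  # radius below the shortest edge: the map is the stimulation vertex alone
  one <- interpolate_to_vertices(data.frame(vertex_id = center, mep_uv = 123),
                                 m, radius_mm = 1.5)
  expect_equal(one$vertex_ids, center)
  expect_equal(one$mep, 123)
  # constant field: any vertex between two equal stimulations gets the value
  v1 <- project_event_to_vertex(c(-4, 0, 0), m)
  v2 <- project_event_to_vertex(c(4, 0, 0), m)
  mp <- interpolate_to_vertices(
    data.frame(vertex_id = c(v1, v2), mep_uv = c(50, 50)), m, radius_mm = 6)
  expect_true(all(abs(mp$mep - 50) < 1e-12))
  # duplicated stimulation vertices are averaged
  dup <- interpolate_to_vertices(
    data.frame(vertex_id = c(center, center), mep_uv = c(10, 30)), m, 1.5)
  expect_equal(dup$mep, 20)
  expect_error(interpolate_to_vertices(data.frame(vertex_id = integer(),
                                                  mep_uv = numeric()), m, 5),
               "empty")
})

test_that("interpolation tracks an analytic Gaussian field", {
  set.seed(61)
  m <- make_flat_patch_mesh(25, 25, 2)
  v <- m$vertices
  f <- gt_field("FDI", c(2, -1, 0), sigma_mm = 6, peak_uv = 800)
  pts <- cbind(runif(120, -12, 12), runif(120, -12, 12), 0)
  vid <- apply(pts, 1, project_event_to_vertex, surface = m)
  stims <- data.frame(vertex_id = vid,
                      mep_uv = vapply(seq_len(nrow(pts)), function(i)
                        sample_field_amplitude(f, pts[i, ]), 0))
  mp <- interpolate_to_vertices(stims, m, radius_mm = 5)
  # exact at stimulation vertices (average when several stims share one)
  agg <- tapply(stims$mep_uv, stims$vertex_id, mean)
  at_stims <- mp$mep[match(as.integer(names(agg)), mp$vertex_ids)]
  expect_equal(at_stims, as.numeric(agg), tolerance = 1e-12)
  # typical off-sample vertices follow the field; the 5 mm smoothing radius
  # leaves a larger bias where the field decays on a comparable scale
  off <- setdiff(mp$vertex_ids, as.integer(names(agg)))
  truth <- vapply(off, function(i)
    sample_field_amplitude(f, v[i, ]), 0)
  got <- mp$mep[match(off, mp$vertex_ids)]
  sel <- truth > 80
  expect_lt(stats::median(abs(got[sel] - truth[sel]) / truth[sel]), 0.15)

  # a field smooth relative to the radius: every interior off-sample vertex
  # is within 15% of the analytic value (120-point sampling lattice)
  f2 <- gt_field("FDI", c(2, -1, 0), sigma_mm = 10, peak_uv = 800)
  lat <- which(v[, 1] %% 4 == 0 & v[, 2] %% 4 == 0 &
                 abs(v[, 1]) <= 20 & abs(v[, 2]) <= 20)
  amp <- vapply(lat, function(i)
    as.numeric(sample_field_amplitude(f2, v[i, ])), 0)
  mp2 <- interpolate_to_vertices(data.frame(vertex_id = lat, mep_uv = amp),
                                 m, radius_mm = 5)
  off2 <- setdiff(mp2$vertex_ids, lat)
  interior <- off2[abs(v[off2, 1]) <= 18 & abs(v[off2, 2]) <= 18]
  truth2 <- vapply(interior, function(i)
    as.numeric(sample_field_amplitude(f2, v[i, ])), 0)
  got2 <- mp2$mep[match(interior, mp2$vertex_ids)]
  keep <- truth2 >= 80
  expect_lt(max(abs(got2[keep] - truth2[keep]) / truth2[keep]), 0.15)
})

test_that("map centroid is the MEP-weighted mean position", {
  m <- make_flat_patch_mesh(3, 3, 1)
  one <- excitability_map(m, 5, 4)
  expect_equal(map_centroid(one), as.numeric(m$vertices[5, ]))

  s <- tri_surface(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0)),
                   matrix(1:3, 1))
  mp <- excitability_map(s, c(1, 2), c(1, 3))
  expect_equal(map_centroid(mp), c(1.5, 0, 0))
  expect_error(map_centroid(excitability_map(s, c(1, 2), c(0, 0))),
               "undefined centroid")
})

test_that("centroid is translation-equivariant and weight-scale invariant", {
  set.seed(62)
  m <- random_bumpy_mesh(6, 6, 1.7)
  ids <- sample(nrow(m$vertices), 12)
  w <- runif(12, 0.1, 5)
  c0 <- map_centroid(excitability_map(m, ids, w))
  shift <- c(3, -7, 2)
  m2 <- m
  m2$vertices <- sweep(m$vertices, 2, -shift)
  expect_equal(map_centroid(excitability_map(m2, ids, w)), c0 + shift)
  expect_equal(map_centroid(excitability_map(m, ids, 10 * w)), c0)
})

test_that("weighted area reduces to Heron geometry", {
  tri <- right_triangle_surface()
  unit <- excitability_map(tri, 1:3, rep(1, 3))
  expect_equal(area_size(unit), 0.5)
  expect_equal(area_size(excitability_map(tri, 1:3, c(1, 2, 3))), 1.0)
  # isolated vertices span no triangle
  m <- make_flat_patch_mesh(5, 5, 1)
  expect_warning(z <- area_size(excitability_map(m, c(1, 13), c(1, 1))),
                 "no complete triangle")
  expect_equal(z, 0)
})

test_that("unit-weight area matches the cross-product oracle", {
  set.seed(63)
  for (i in 1:50) {
    m <- random_bumpy_mesh(sample(3:8, 1), sample(3:8, 1), runif(1, 0.5, 3))
    full <- excitability_map(m, seq_len(nrow(m$vertices)),
                             rep(1, nrow(m$vertices)))
    expect_equal(area_size(full), sum(triangle_areas(m)),
                 tolerance = 1e-9)
  }
})

test_that("overlap obeys the intersection-over-union identities", {
  m <- make_flat_patch_mesh(7, 7, 1)
  all_ids <- seq_len(nrow(m$vertices))
  a <- excitability_map(m, all_ids[m$vertices[, 1] <= 0], rep(1, sum(m$vertices[, 1] <= 0)))
  expect_equal(map_overlap(a, a), 1)
  b <- excitability_map(m, all_ids[m$vertices[, 1] >= 2],
                        rep(2, sum(m$vertices[, 1] >= 2)))
  expect_equal(map_overlap(a, b), 0)
  expect_error(map_overlap(a, excitability_map(make_flat_patch_mesh(3, 3, 1),
                                               1:3, rep(1, 3))),
               "same template")
  iso <- excitability_map(m, c(1, 10), c(1, 1))
  expect_error(map_overlap(iso, iso), "empty union")
})

test_that("equal-area triangle sets {A,B} vs {B,C} overlap by one third", {
  # three identical right triangles in a strip of the unit-spacing patch
  s <- tri_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0),
                         c(0, 1, 0), c(1, 1, 0), c(2, 1, 0), c(3, 1, 0)),
                   rbind(c(1, 2, 5), c(2, 3, 6), c(3, 4, 7)))
  mk <- excitability_map(s, c(1, 2, 5, 3, 6), rep(1, 5)) # triangles A, B
  ml <- excitability_map(s, c(2, 3, 6, 4, 7), rep(1, 5)) # triangles B, C
  expect_equal(map_overlap(mk, ml), 1 / 3)
})

test_that("overlap is symmetric and bounded in both modes", {
  set.seed(64)
  m <- make_flat_patch_mesh(8, 8, 1)
  for (i in 1:10) {
    ka <- sample(nrow(m$vertices), 25)
    kb <- sample(nrow(m$vertices), 25)
    a <- excitability_map(m, ka, runif(25, 0.1, 9))
    b <- excitability_map(m, kb, runif(25, 0.1, 9))
    tk <- tmsmap:::complete_triangles(m, ka)
    tl <- tmsmap:::complete_triangles(m, kb)
    if (length(union(tk, tl)) == 0) next
    for (mode in c("geometric", "weighted")) {
      o1 <- map_overlap(a, b, mode)
      o2 <- map_overlap(b, a, mode)
      expect_equal(o1, o2, tolerance = 1e-12)
      expect_gte(o1, 0)
      expect_lte(o1, 1)
    }
  }
})

test_that("growing the intersection inside a fixed union never lowers overlap", {
  m <- make_flat_patch_mesh(9, 3, 1)
  v <- m$vertices
  cols <- sort(unique(v[, 1]))
  full <- seq_len(nrow(v))
  prev <- -1
  for (w in 3:7) {
    a <- excitability_map(m, full[v[, 1] <= cols[w]],
                          rep(1, sum(v[, 1] <= cols[w])))
    b <- excitability_map(m, full, rep(1, nrow(v))) # union fixed: everything
    o <- map_overlap(a, b)
    expect_gte(o, prev)
    prev <- o
  }
})

test_that("geometric overlap of half-maximum discs matches the lens formula", {
  r <- 6 * sqrt(2 * log(2))
  disc_overlap_on <- function(spacing, d) {
    n <- round(40 / spacing) + 1
    m <- make_flat_patch_mesh(n, n, spacing)
    v <- m$vertices
    i1 <- which(sqrt((v[, 1] + d / 2)^2 + v[, 2]^2) <= r)
    i2 <- which(sqrt((v[, 1] - d / 2)^2 + v[, 2]^2) <= r)
    map_overlap(excitability_map(m, i1, rep(1, length(i1))),
                excitability_map(m, i2, rep(1, length(i2))))
  }
  # wide lens: accurate already at 1 mm spacing
  expect_equal(disc_overlap_on(1, 4), disc_jaccard(4, r, r),
               tolerance = 0.1)
  # thinner lens: the complete-triangle rule under-counts the pointy
  # intersection; the estimate must converge towards the analytic value
  # under mesh refinement
  a8 <- disc_jaccard(8, r, r)
  e_coarse <- abs(disc_overlap_on(1, 8) - a8)
  e_fine <- abs(disc_overlap_on(0.5, 8) - a8)
  expect_lt(e_fine, e_coarse)
})

test_that("the 28 muscle pairs partition into 6/16/6 with 13 synergists", {
  pg <- pair_grouping()
  expect_equal(nrow(pg), 28)
  counts <- table(pg$pair_group)
  expect_equal(as.vector(counts[c("hand-hand", "hand-forearm",
                                  "forearm-forearm")]), c(6, 16, 6))
  expect_equal(sum(pg$synergistic[pg$pair_group == "hand-hand"]), 3)
  expect_equal(sum(pg$synergistic[pg$pair_group == "forearm-forearm"]), 2)
  expect_equal(sum(pg$synergistic[pg$pair_group == "hand-forearm"]), 8)
  syn_hf <- pg[pg$pair_group == "hand-forearm" & pg$synergistic, ]
  expect_true(all(syn_hf$muscle_k %in% c("EDC", "FDS") |
                    syn_hf$muscle_l %in% c("EDC", "FDS")))
  expect_error(pair_grouping(c(muscle_labels()[-1], "BIC")), "unknown muscle")
})
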