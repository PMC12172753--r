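test_that("tri_surface enforces its invariants", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(tri_surface(v, matrix(c(1, 2, 4), 1)), "out of range")
  expect_error(tri_surface(rbind(v, c(2, 0, 0)),
                           rbind(c(1, 2, 3), c(1, 2, 4), c(2, 4, 2))),
               "degenerate")
  expect_error(tri_surface(v, matrix(1:3, 1), sphere = v), "unit norm")
  s <- tri_surface(v, matrix(1:3, 1), curvature = rep(0, 3),
                   sphere = rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)))
  expect_s3_class(s, "tri_surface")
})

test_that("plain-text mesh round-trips through its dialect", {
  m <- make_flat_patch_mesh(4, 3, 1.5, region_halfwidth_mm = 1)
  m$curvature <- rnorm(nrow(m$vertices))
  path <- withr::local_tempfile(fileext = ".txt")
  write_mesh_txt(m, path)
  # faces are 0-based on disk
  lines <- readLines(path)
  first_face <- as.integer(strsplit(lines[2 + nrow(m$vertices)], " ")[[1]])
  expect_equal(first_face, m$faces[1, ] - 1L)
  r <- read_mesh_txt(path)
  expect_equal(r$vertices, m$vertices, tolerance = 1e-7, ignore_attr = TRUE)
  expect_identical(r$faces, m$faces)
  expect_equal(r$curvature, m$curvature, tolerance = 1e-7)
  expect_identical(r$atlas_labels, m$atlas_labels)
})

test_that("FreeSurfer binary surface and curv files round-trip", {
  m <- make_hemisphere_mesh(1, 25)
  sp <- withr::local_tempfile()
  write_fs_surface(m, sp)
  r <- read_fs_surface(sp)
  expect_equal(r$vertices, m$vertices, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(r$faces, m$faces)

  cp <- withr::local_tempfile()
  curv <- rnorm(nrow(m$vertices))
  write_fs_curv(curv, cp, n_faces = nrow(m$faces))
  expect_equal(read_fs_curv(cp), curv, tolerance = 1e-6)
  expect_error(read_fs_curv(sp), "curv")
  expect_error(read_fs_surface(cp), "triangle surface")
})

test_that("GIFTI surfaces read in ASCII and base64 encodings", {
  m <- make_flat_patch_mesh(3, 3, 2)
  gp <- withr::local_tempfile(fileext = ".surf.gii")
  write_gifti_surface(m, gp)
  r <- read_gifti_surface(gp)
  expect_equal(r$vertices, m$vertices, ignore_attr = TRUE)
  expect_identical(r$faces, m$faces)

  # hand-built little-endian GZipBase64Binary variant
  enc <- function(x, what) jsonlite::base64_enc(memCompress(
    writeBin(if (what == "f") as.numeric(x) else as.integer(x),
             raw(), size = 4, endian = "little"), "gzip"))
  vt <- t(m$vertices)
  ft <- t(m$faces - 1L)
  xml <- paste0(
    '<?xml version="1.0"?><GIFTI Version="1.0" NumberOfDataArrays="2">',
    '<DataArray Intent="NIFTI_INTENT_POINTSET" DataType="NIFTI_TYPE_FLOAT32"',
    ' Dim0="', nrow(m$vertices), '" Dim1="3" Encoding="GZipBase64Binary"',
    ' Endian="LittleEndian"><Data>', enc(as.vector(vt), "f"),
    '</Data></DataArray>',
    '<DataArray Intent="NIFTI_INTENT_TRIANGLE" DataType="NIFTI_TYPE_INT32"',
    ' Dim0="', nrow(m$faces), '" Dim1="3" Encoding="GZipBase64Binary"',
    ' Endian="LittleEndian"><Data>', enc(as.vector(ft), "i"),
    '</Data></DataArray></GIFTI>')
  gp2 <- withr::local_tempfile(fileext = ".surf.gii")
  writeLines(xml, gp2)
  r2 <- read_gifti_surface(gp2)
  expect_equal(r2$vertices, m$vertices, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(r2$faces, m$faces)
})

test_that("atlas label sidecars attach by 0-based vertex id", {
  m <- make_flat_patch_mesh(3, 3, 1)
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(vertex_id = c(0, 4, 8), label = "precentral L"),
            p, row.names = FALSE)
  m2 <- attach_labels_csv(m, p)
  expect_equal(which(m2$atlas_labels == "precentral L"), c(1, 5, 9))
  expect_equal(sum(m2$atlas_labels == "other"), 6)
})

test_that("events project to the nearest vertex with low-index ties", {
  m <- make_flat_patch_mesh(5, 5, 2)
  expect_equal(project_event_to_vertex(m$vertices[5, ], m), 5)
  # midpoint between vertices 1 and 2 ties to the lower index
  mid <- (m$vertices[1, ] + m$vertices[2, ]) / 2
  expect_equal(project_event_to_vertex(mid, m), 1)
  set.seed(51)
  bumpy <- random_bumpy_mesh(6, 7, 1.3)
  for (i in 1:200) {
    p <- c(runif(2, -4, 4), runif(1, -1, 1))
    d <- sqrt(colSums((t(bumpy$vertices) - p)^2))
    expect_equal(project_event_to_vertex(p, bumpy), which.min(d))
  }
  ev <- data.frame(x_mm = 0, y_mm = 0, z_mm = 0)
  expect_equal(project_event_to_vertex(ev[1, ], m),
               project_event_to_vertex(c(0, 0, 0), m))
})

test_that("region masking filters by atlas label", {
  m <- make_flat_patch_mesh(5, 2, 1, region_halfwidth_mm = Inf)
  expect_equal(mask_to_region(1:10, m), 1:10)
  m$atlas_labels <- rep("other", 10)
  expect_warning(out <- mask_to_region(1:10, m), "labels no vertex")
  expect_equal(length(out), 0)
  m$atlas_labels <- rep(c("precentral L", "other"), 5)
  expect_equal(mask_to_region(1:10, m), c(1, 3, 5, 7, 9))
  # disabled masking is the identity
  expect_equal(mask_to_region(1:10, m, enabled = FALSE), 1:10)
  m$atlas_labels <- NULL
  expect_error(mask_to_region(1:3, m), "atlas labels")
})

test_that("warping a surface onto itself is the identity", {
  for (m in list(make_flat_patch_mesh(6, 6, 2), make_hemisphere_mesh(2, 9))) {
    idx <- seq_len(nrow(m$vertices))
    expect_equal(warp_vertices(idx, m, m, lambda_curv = 0), idx)
    expect_equal(warp_vertices(idx, m, m, lambda_curv = 1), idx)
  }
})

test_that("warping recovers a known sphere rotation", {
  m <- make_hemisphere_mesh(2, 10)
  ang <- 0.3
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  template <- m
  template$sphere <- m$sphere %*% t(R) # template sphere is rotated subject
  got <- warp_vertices(seq_len(nrow(m$vertices)), m, template,
                       lambda_curv = 0)
  # oracle: exhaustive nearest template-sphere vertex to R^-1-rotated ...
  # equivalently max dot product with the rotated registration
  oracle <- apply(m$sphere %*% t(template$sphere), 1, which.max)
  expect_equal(got, as.integer(oracle))
})

test_that("a dominant curvature penalty selects the curvature match", {
  m <- make_flat_patch_mesh(4, 4, 1)
  template <- m
  m$curvature <- rep(0, 16); m$curvature[3] <- 5
  template$curvature <- rep(0, 16); template$curvature[12] <- 5
  expect_equal(warp_vertex(3, m, template, lambda_curv = 1e6), 12L)
  m$sphere <- NULL
  expect_error(warp_vertex(1, m, template), "sphere registration")
})

test_that("warping events conserves amplitudes", {
  m <- make_flat_patch_mesh(6, 6, 2)
  stims <- data.frame(vertex_id = c(3, 9, 9, 20), mep_uv = c(5, 10, 2, 8))
  w <- warp_events(stims, m, m, lambda_curv = 0)
  expect_equal(w$vertex_id, stims$vertex_id)
  expect_equal(sum(w$mep_uv), sum(stims$mep_uv))
  template <- m
  template$vertices <- m$vertices + 100 # same sphere, shifted space
  w2 <- warp_events(stims, m, template, lambda_curv = 0)
  expect_equal(sum(w2$mep_uv), sum(stims$mep_uv))
})

test_that("geodesic distances behave like a metric on the mesh graph", {
  m <- make_flat_patch_mesh(4, 4, 2)
  d <- geodesic_distances(m, c(1, 6))
  expect_equal(d[1, 1], 0)
  expect_equal(d[2, 6], 0)
  expect_equal(d[1, 2], 2) # adjacent along the grid
  d_all <- geodesic_distances(m, seq_len(nrow(m$vertices)))
  expect_equal(d_all, t(d_all))
})
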