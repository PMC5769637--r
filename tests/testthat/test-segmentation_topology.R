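# 15x15 label image: a 5x5 mosaic of 3x3-pixel square cells, labels 1..25
mosaic_5x5 <- function() {
  cell_of <- function(i) (i - 1) %/% 3 + 1
  L <- outer(1:15, 1:15, function(r, c) (cell_of(r) - 1) * 5 + cell_of(c))
  segmented_frame(matrix(as.integer(L), 15, 15))
}

test_that("label images round-trip bit-exactly through TIFF and PNG", {
  set.seed(81)
  m <- matrix(sample(c(0:5, 60000:65535), 144, replace = TRUE), 12, 12)
  tf <- tempfile(fileext = ".tif")
  write_label_image(m, tf)
  fr <- read_label_image(tf)
  expect_identical(fr$labels, m)

  m8 <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  pf <- tempfile(fileext = ".png")
  png::writePNG(m8 / 255, pf)
  fr8 <- read_label_image(pf)
  expect_identical(fr8$labels, m8)

  # 3 labels -> 3 cell records
  toy <- segmented_frame(matrix(c(1L, 1L, 2L, 3L), 2, 2))
  expect_equal(nrow(analyze_frame(toy)$cells), 3L)
})

test_that("malformed images are rejected and empty ones warned about", {
  rgb <- tempfile(fileext = ".png")
  png::writePNG(array(stats::runif(27), c(3, 3, 3)), rgb)
  expect_error(read_label_image(rgb), "RGB")
  expect_error(read_label_image("x.bmp"), "unsupported")
  expect_error(segmented_frame(matrix(c(0.5, 1, 2, 3), 2, 2)),
               "non-integer")
  expect_warning(segmented_frame(matrix(0L, 4, 4)), "empty")
})

test_that("adjacency uses 4-connectivity, never corner contact", {
  checker <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  adj <- build_adjacency(checker)
  expect_equal(adj[["1"]], 2L)
  expect_equal(adj[["2"]], 1L)

  diag_only <- matrix(c(1L, 0L, 0L, 2L), 2, 2)
  adj2 <- build_adjacency(diag_only)
  expect_length(adj2[["1"]], 0L)
  expect_length(adj2[["2"]], 0L)

  # one-pixel background membrane bridged only in membrane mode
  mem <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L, 2L, 2L, 2L), 3, 3)
  expect_length(build_adjacency(mem)[["1"]], 0L)
  expect_equal(build_adjacency(mem, membrane = 1)[["1"]], 2L)

  # symmetry on a real mosaic
  adj3 <- analyze_frame(mosaic_5x5())$adjacency
  for (i in names(adj3))
    for (j in adj3[[i]])
      expect_true(as.integer(i) %in% adj3[[as.character(j)]])
  # centre cell of the mosaic has exactly its 4 edge-sharing neighbours
  expect_equal(adj3[["13"]], c(8L, 12L, 14L, 18L))
})

test_that("validity tiers are nested and follow the boundary rules", {
  fr <- analyze_frame(mosaic_5x5())
  cells <- fr$cells
  border_ids <- c(1:5, 6, 10, 11, 15, 16, 20, 21:25)
  expect_setequal(cells$id[cells$touches_border], border_ids)
  expect_setequal(cells$id[cells$interior], setdiff(1:25, border_ids))
  # only the centre cell has all neighbours interior
  expect_equal(cells$id[cells$neighbour_complete], 13L)
  # and its neighbours are not neighbour-complete, so no second-order cell
  expect_false(any(cells$second_order_complete))
  expect_true(all(cells$interior[cells$neighbour_complete]))

  # a single cell filling the image touches the border and is excluded
  one <- analyze_frame(segmented_frame(matrix(1L, 6, 6)))
  expect_true(one$cells$touches_border)
  expect_false(one$cells$interior)
})

test_that("geometry reports exact areas and moment-based axes", {
  L <- matrix(0L, 30, 30)
  L[3:12, 3:12] <- 1L   # 10x10 square
  L[16:20, 5:24] <- 2L  # 5 rows x 20 cols rectangle
  L[25, 25] <- 3L       # degenerate single pixel
  fr <- segmented_frame(L)
  geo <- geometry(fr)
  sq <- geo[geo$id == 1L, ]
  expect_equal(sq$area, 100)
  expect_equal(sq$anisotropy, 1)
  expect_equal(sq$centroid_x, 7.5)
  expect_equal(sq$centroid_y, 7.5)
  rect <- geo[geo$id == 2L, ]
  expect_equal(rect$area, 100)
  expect_equal(rect$anisotropy, 4)
  expect_equal(rect$major, 4 * sqrt(400 / 12))
  px <- geo[geo$id == 3L, ]
  expect_equal(px$anisotropy, 1)
  expect_true(px$degenerate)

  # pixel-size scaling: areas in physical units
  geo2 <- geometry(segmented_frame(L, pixel_size = 0.5))
  expect_equal(geo2$area[geo2$id == 1L], 25)

  # random blob: area equals the direct pixel count
  set.seed(91)
  B <- matrix(0L, 20, 20)
  B[sample(400, 57)] <- 4L
  expect_equal(geometry(segmented_frame(B))$area, 57)

  # area conservation over a full frame
  fr5 <- mosaic_5x5()
  expect_equal(sum(geometry(fr5)$area) + sum(fr5$labels == 0L), 15 * 15)
})

test_that("statistics are invariant under image transposition", {
  set.seed(95)
  sf <- voronoi_frame(synthetic_frame_spec(30, c(90, 90), seed = 4))
  a <- analyze_frame(sf$frame)$cells
  b <- analyze_frame(segmented_frame(t(sf$frame$labels)))$cells
  expect_equal(a$n, b$n)
  expect_equal(a$area, b$area)
  expect_equal(a$anisotropy, b$anisotropy)
  expect_equal(a$neighbour_complete, b$neighbour_complete)
  expect_equal(a$centroid_x, b$centroid_y)
})

test_that("heat maps recolour cells without touching label geometry", {
  fr <- analyze_frame(mosaic_5x5())
  out <- tempfile(fileext = ".png")
  export_heatmap(fr, "n", out)
  expect_true(file.exists(out))
  img <- png::readPNG(out)
  expect_equal(dim(img)[1:2], dim(fr$labels))
  # within every cell the colour is uniform (labels unchanged)
  for (id in c(1L, 13L, 25L)) {
    sel <- fr$labels == id
    for (ch in 1:3)
      expect_equal(stats::sd(img[, , ch][sel]), 0)
  }
  # the only valid cell (n = 4) sits in the sub-6 band, others are grey
  centre <- fr$labels == 13L
  border <- fr$labels == 1L
  expect_equal(unique(img[, , 1][border]), 0.5, tolerance = 0.01)
  expect_false(isTRUE(all.equal(img[, , 1][centre][1], 0.5,
                                tolerance = 0.01)))
  expect_error(export_heatmap(fr, "volume", tempfile()), "arg")
})
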