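test_that("structured grids have closed-form node and element counts", {
  for (nm in list(c(3, 2), c(10, 10), c(7, 1))) {
    g <- structured_grid(10, 5, nm[1], nm[2])
    expect_equal(nrow(g$elements), nm[1] * nm[2])
    expect_equal(nrow(g$nodes), (nm[1] + 1) * (nm[2] + 1))
  }
  q <- mesh_quality(structured_grid(10, 10, 10, 10))
  expect_equal(q$element_count, 100L)
  expect_equal(q$node_count, 121L)
})

test_that("the layered domain is conforming where bonded, split where in contact", {
  spec <- domain_spec() # TSF-thickness dressing by default
  mesh <- build_layered_domain(spec, mesh_control())
  # dressing spans exactly its nominal thickness
  de <- which(mesh$region == "dressing")
  ys <- mesh$nodes[unique(as.vector(mesh$elements[de, ])), 2]
  expect_equal(diff(range(ys)), 5.50, tolerance = 1e-12)
  # dressing-tissue interface nodes are shared: no duplicated coordinates
  iface <- mesh$sets$dressing_tissue_interface
  expect_gt(length(iface), 0)
  key <- paste(round(mesh$nodes[, 1], 9), round(mesh$nodes[, 2], 9))
  expect_false(any(duplicated(key[iface])))
  ifkey <- key[iface]
  expect_equal(sum(key %in% ifkey), length(iface))
  # dressing-mattress interface is a contact pair: distinct coincident nodes
  expect_gt(length(intersect(
    paste(round(mesh$nodes[mesh$sets$mattress_top, 1], 9)),
    paste(round(mesh$nodes[mesh$sets$dressing_bottom, 1], 9)))), 0)
  expect_length(intersect(mesh$sets$mattress_top, mesh$sets$dressing_bottom),
                0)
  # regions partition the elements; all sets reference valid nodes
  expect_setequal(unique(mesh$region),
                  c("mattress", "dressing", "tissue", "bone"))
  expect_gt(sum(mesh$region == "bone"), 0)
})

test_that("geometry and resolution preconditions are enforced", {
  expect_error(domain_spec(prominence_depth = 50, prominence_tip_radius = 20),
               "geometry error")
  expect_error(domain_spec(dressing_extent = 300), "dressing_extent")
  expect_error(domain_spec(tissue_width = -1), "tissue_width")
  # fewer than 2 elements across a layer
  expect_error(build_layered_domain(domain_spec(), resolution = 0.05),
               "resolution error")
})

test_that("element volumes match an independent triangulation oracle", {
  set.seed(41)
  # random valid convex-ish quadrilateral
  for (i in 1:20) {
    pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)) +
      matrix(stats::runif(8, -0.2, 0.2), 4, 2)
    m <- fea_mesh(pts, matrix(1:4, 1), "tissue")
    # split along a diagonal into two triangles
    tri_area <- function(a, b, c) {
      0.5 * abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2]))
    }
    expect_equal(element_volumes(m),
                 tri_area(pts[1, ], pts[2, ], pts[3, ]) +
                   tri_area(pts[1, ], pts[3, ], pts[4, ]),
                 tolerance = 1e-12)
  }
})

test_that("volumes respond exactly to affine deformation", {
  m <- structured_grid(1, 1, 1, 1)
  expect_equal(element_volumes(m), 1)
  # uniform 2x stretch in x doubles the volume
  u <- cbind(m$nodes[, 1], 0)
  expect_equal(element_volumes(m, u), 2)
  # inverted configuration errors with the element index
  ubad <- cbind(0, -3 * m$nodes[, 2])
  expect_error(element_volumes(m, ubad), "inverted")
})

test_that("region volumes sum to the domain volume", {
  spec <- domain_spec()
  for (res in list(mesh_control(), c(x = 0.2, tissue = 0.2, dressing = 0.4,
                                     mattress = 0.12))) {
    mesh <- build_layered_domain(spec, res)
    v <- element_volumes(mesh)
    expect_true(all(v > 0))
    expected <- spec$tissue_width * spec$tissue_height +
      spec$tissue_width * spec$mattress_thickness +
      diff(range(mesh$nodes[mesh$sets$dressing_bottom, 1])) *
      spec$dressing_thickness
    expect_equal(sum(v), expected, tolerance = 1e-9)
    expect_gt(mesh_quality(mesh)$min_jacobian, 0)
  }
})

test_that("uniform refinement multiplies structured region counts by four", {
  spec <- domain_spec(dressing_thickness = 0, prominence_tip_radius = 0)
  # sizes chosen so layer thickness x resolution is an integer: doubling
  # the resolution then exactly doubles each direction
  res <- c(x = 0.08, tissue = 0.08, mattress = 0.08)
  m1 <- build_layered_domain(spec, res)
  m2 <- build_layered_domain(spec, 2 * res)
  for (reg in c("tissue", "mattress")) {
    expect_identical(sum(m2$region == reg), 4L * sum(m1$region == reg))
  }
})

test_that("degenerate elements are flagged by the quality report", {
  pts <- rbind(c(0, 0), c(1, 0), c(1, 0), c(0, 1)) # two coincident nodes
  m <- fea_mesh(pts, matrix(1:4, 1), "tissue")
  expect_lte(mesh_quality(m)$min_jacobian, 0)
  q <- mesh_quality(structured_grid(1, 1, 1, 1))
  expect_equal(q$min_jacobian, 1, tolerance = 1e-12)
  expect_equal(q$max_aspect_ratio, 1, tolerance = 1e-12)
})

test_that("mesh text format round-trips", {
  mesh <- build_layered_domain(domain_spec(), c(x = 0.1, tissue = 0.1,
                                                dressing = 0.4,
                                                mattress = 0.08))
  path <- withr::local_tempfile(fileext = ".txt")
  write_mesh(mesh, path)
  back <- read_mesh(path)
  expect_equal(back$nodes, mesh$nodes, tolerance = 1e-12)
  expect_identical(back$elements, mesh$elements)
  expect_identical(back$region, mesh$region)
  expect_identical(lapply(back$sets, as.integer), lapply(mesh$sets,
                                                         as.integer))
  expect_equal(back$depth, mesh$depth)
})

test_that("VTK export writes a readable unstructured grid", {
  mesh <- structured_grid(2, 1, 4, 2)
  path <- withr::local_tempfile(fileext = ".vtk")
  vals <- seq_len(nrow(mesh$elements)) / 10
  write_vtk(mesh, path, cell_data = list(sed = vals))
  lines <- readLines(path)
  expect_identical(lines[1], "# vtk DataFile Version 2.0")
  expect_true(any(grepl("^CELLS 8 40$", lines)))
  expect_equal(read_vtk_cell_field(path, "sed"), vals, tolerance = 1e-8)
})

test_that("coarse 3-D extrusion keeps counts and volume", {
  spec <- domain_spec(dimensionality = "3D", tissue_depth = 100)
  res <- c(x = 0.15, tissue = 0.15, dressing = 0.4, mattress = 0.04,
           z = 0.03)
  m3 <- build_layered_domain(spec, res)
  expect_equal(m3$dim, 3L)
  expect_equal(ncol(m3$elements), 8L)
  v <- element_volumes(m3)
  expect_true(all(v > 0))
  m2 <- build_layered_domain(domain_spec(), res[1:4])
  v2 <- element_volumes(m2)
  expect_equal(sum(v), sum(v2) * 100, tolerance = 1e-9)
  expect_gt(mesh_quality(m3)$min_jacobian, 0)
  expect_true(any(m3$region == "bone"))
})
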