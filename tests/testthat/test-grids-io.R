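test_that("density_grid validates geometry and degenerate dimensions", {
  g <- density_grid(c(1, 2, 3))
  expect_equal(dim(g$values), c(3L, 1L, 1L))
  gm <- density_grid(matrix(1:6, 2, 3), spacing = 0.5)
  expect_equal(dim(gm$values), c(2L, 3L, 1L))
  expect_error(density_grid(array(0, c(2, 2, 2)), spacing = 0),
               "strictly positive")
  expect_error(density_grid(array(c(1, NA), c(2, 1, 1))), "finite")
  g2 <- density_grid(array(0, c(10, 10, 10)), origin = c(0, 0, 0))
  expect_equal(grid_box_center(g2), c(4.5, 4.5, 4.5))
  expect_equal(grid_axis_centers(g2, 1)[3], 2)
})

test_that("MRC write/read round-trips values, origin and spacing", {
  set.seed(11)
  g <- density_grid(array(rnorm(8 * 6 * 4), c(8, 6, 4)),
                    origin = c(-3.5, 2, 0.25), spacing = 1.31)
  path <- tempfile(fileext = ".mrc")
  write_map(g, path)
  g2 <- read_map(path)
  expect_equal(dim(g2$values), dim(g$values))
  # float32 storage precision
  expect_lt(max(abs(g2$values - g$values)), 1e-6 * max(abs(g$values)))
  expect_equal(g2$origin, g$origin, tolerance = 1e-6)
  expect_equal(g2$spacing, g$spacing, tolerance = 1e-6)
})

test_that("an all-zero 8^3 map reads back with zero sum and 1-voxel-thick grids survive", {
  g <- density_grid(array(0, c(8, 8, 8)), spacing = 1)
  p <- tempfile(fileext = ".mrc")
  write_map(g, p)
  expect_equal(sum(read_map(p)$values), 0)
  thin <- density_grid(array(stats::runif(25), c(5, 5, 1)), spacing = 2)
  p2 <- tempfile(fileext = ".mrc")
  write_map(thin, p2)
  expect_equal(dim(read_map(p2)$values), c(5L, 5L, 1L))
})

test_that("header statistics match recomputed min/max", {
  set.seed(4)
  g <- density_grid(array(rnorm(27), c(3, 3, 3)))
  p <- tempfile(fileext = ".mrc")
  write_map(g, p)
  con <- file(p, "rb")
  hdr <- readBin(con, "numeric", n = 22, size = 4, endian = "little")
  close(con)
  expect_equal(hdr[20], min(g$values), tolerance = 1e-6)
  expect_equal(hdr[21], max(g$values), tolerance = 1e-6)
})

test_that("permuted-axis MRC files are normalized to canonical X,Y,Z order", {
  set.seed(5)
  vals <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  g <- density_grid(vals, origin = c(0, 0, 0), spacing = 2)
  # hand-write the same volume with MAPC,MAPR,MAPS = 3,1,2 (file axes
  # run z fastest), independent of the package writer
  perm_path <- tempfile(fileext = ".mrc")
  con <- file(perm_path, "wb")
  wi <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4,
                             endian = "little")
  wi(c(5, 3, 4))                    # file dims: (z, x, y)
  wi(2)
  wi(c(0, 0, 0))
  wi(c(3, 4, 5))                    # MX,MY,MZ along X,Y,Z
  wf(c(3, 4, 5) * 2)                # CELLA
  wf(c(90, 90, 90))
  wi(c(3, 1, 2))                    # MAPC,MAPR,MAPS
  wf(c(min(vals), max(vals), mean(vals)))
  wi(c(1, 0)); wi(rep(0L, 25)); wf(c(0, 0, 0))
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(0); wi(0)
  writeChar(paste(rep(" ", 800), collapse = ""), con, nchars = 800,
            eos = NULL)
  wf(aperm(vals, c(3, 1, 2)))       # data with z fastest
  close(con)
  gp <- read_map(perm_path)
  expect_equal(gp$values, g$values, tolerance = 1e-6)
  expect_equal(gp$spacing, g$spacing, tolerance = 1e-6)
})

test_that("maps written here are readable by an external MRC implementation", {
  gemmi_ok <- tryCatch({
    out <- suppressWarnings(system2("python", c("-c", "import gemmi"),
                                    stdout = TRUE, stderr = TRUE))
    is.null(attr(out, "status"))
  }, error = function(e) FALSE)
  if (!gemmi_ok) {
    succeed("external MRC reader not available; round-trip covered above")
    return(invisible())
  }
  set.seed(6)
  g <- density_grid(array(rnorm(4 * 4 * 4), c(4, 4, 4)),
                    origin = c(1, 2, 3), spacing = 1.5)
  p <- tempfile(fileext = ".mrc")
  write_map(g, p)
  script <- sprintf(
    "import gemmi, json; m = gemmi.read_ccp4_map('%s'); g = m.grid; print(json.dumps({'sum': float(sum(g.array.flatten().tolist())), 'shape': list(g.array.shape), 'spacing': m.grid.unit_cell.a / g.nu}))",
    p)
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  parsed <- jsonlite::fromJSON(out)
  expect_equal(parsed$sum, sum(g$values), tolerance = 1e-5)
  expect_equal(sort(parsed$shape), c(4, 4, 4))
  expect_equal(parsed$spacing, 1.5, tolerance = 1e-6)
})

test_that("PDB reading assigns unit amplitudes to heavy atoms and zero to hydrogens", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      10.000  20.000  30.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.500  20.000  30.000  1.00  0.00           C",
    "ATOM      3  H   ALA A   1      12.000  21.000  30.500  1.00  0.00           H",
    "END"), pdb)
  at <- read_structure(pdb)
  expect_equal(n_atoms(at), 3L)
  expect_equal(at$amplitudes, c(1, 1, 0))
  expect_equal(at$positions[1, ], c(10, 20, 30))
})

test_that("hydrogens are recognized from atom names when the element column is absent", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      10.000  20.000  30.000  1.00  0.00",
    "ATOM      2  HA  ALA A   1      12.000  21.000  30.500  1.00  0.00",
    "END"), pdb)
  at <- read_structure(pdb)
  expect_equal(at$amplitudes, c(1, 0))
})

test_that("centering places the center of geometry at the box center and is a rigid translation", {
  g <- make_geom(c(10, 10, 10))
  one <- atom_set(c(100, -50, 3))
  expect_equal(center_in_grid(one, g)$positions[1, ], c(4.5, 4.5, 4.5))
  two <- atom_set(rbind(c(0, 0, 0), c(2, 0, 0)))
  cen <- center_in_grid(two, g)
  expect_equal(sqrt(sum((cen$positions[1, ] - cen$positions[2, ])^2)), 2)
  # idempotence
  again <- center_in_grid(cen, g)
  expect_equal(again$positions, cen$positions)
  # pairwise distances preserved exactly for a larger random set
  set.seed(8)
  many <- atom_set(matrix(rnorm(30, sd = 5), 10, 3))
  cm <- center_in_grid(many, g)
  expect_equal(as.vector(dist(cm$positions)),
               as.vector(dist(many$positions)))
  expect_error(center_in_grid(atom_set(matrix(numeric(0), 0, 3)), g),
               "empty")
})
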