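# Mesh construction, frame conventions, and propagation across panels.

two_tri <- function(L = 1, labels = c("fast", "slow")) {
  build_mesh(list(rbind(c(0, 0, 0), c(L, 0, 0), c(L, L, 0)),
                  rbind(c(0, 0, 0), c(L, L, 0), c(0, L, 0))), labels)
}

# the same square folded by 90 degrees about its diagonal (non-planar mesh)
folded_tri <- function() {
  # panel 2 is panel 1's mirror rotated out of plane about the diagonal
  build_mesh(list(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
                  rbind(c(0, 0, 0), c(1, 1, 0),
                        c(0.5 + 0.5 / sqrt(2), 0.5 - 0.5 / sqrt(2), -1 / sqrt(2)))),
             c("a", "b"))
}

test_that("edge matching finds shared and boundary edges", {
  m <- two_tri()
  expect_equal(sum(m$edge_nb > 0) / 2, 1)        # one shared edge (the diagonal)
  expect_equal(sum(m$edge_nb == 0), 4)           # four reflective boundary edges
  expect_equal(unname(m$surface_area), c(0.5, 0.5))

  single <- build_mesh(list(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))))
  expect_equal(sum(single$edge_nb == 0), 3)

  # adjacency is symmetric
  for (p in 1:m$np) for (k in 1:3) {
    q <- m$edge_nb[p, k]
    if (q > 0) expect_equal(m$edge_nb[q, m$edge_nbe[p, k]], p)
  }
})

test_that("degenerate meshes are rejected", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(build_mesh(list(tri, tri)), "more than")
  expect_error(build_mesh(list(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)))),
               "degenerate")
  flat_shared <- list(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      rbind(c(0, 0, 0), c(1, 0, 0), c(0, -1, 0)),
                      rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1)))
  expect_error(build_mesh(flat_shared), "more than 2 panels")
})

test_that("to_world honours the frame convention and inverts from_world", {
  m <- two_tri()
  expect_equal(to_world(surface_position(1, c(0, 0)), m), c(0, 0, 0))
  expect_equal(to_world(surface_position(2, c(0, 0)), m), c(0, 0, 0))
  # centroid in barycentric coordinates = mean of the vertices
  for (p in 1:2) {
    cen <- bary_to_local(m, p, c(1, 1, 1))
    expect_equal(to_world(surface_position(p, cen), m),
                 colMeans(m$vertices[[p]]), tolerance = 1e-12)
  }
  expect_error(to_world(surface_position(9, c(0, 0)), m), "unknown panel")

  set.seed(101)
  fm <- folded_tri()
  for (i in 1:1000) {
    p <- sample(1:2, 1)
    w <- c(runif(3)); w <- w / sum(w)
    loc <- bary_to_local(fm, p, w)
    pt <- to_world(surface_position(p, loc), fm)
    back <- from_world(pt, fm, p)
    expect_lt(max(abs(back$local - loc)), 1e-9)
  }
})

test_that("propagation: in-panel, coplanar unfolding, and reflection", {
  m <- two_tri()
  # fully inside the panel
  r <- propagate(surface_position(1, c(0.6, 0.1)), c(0.1, 0.05), m)
  expect_equal(r$position$local, c(0.7, 0.15))
  expect_equal(nrow(r$crossings), 0)
  # crossing the diagonal of a flat square = straight-line planar motion
  r <- propagate(surface_position(1, c(0.8, 0.1)), c(-0.6, 0.5), m)
  expect_equal(r$crossings$surface, "slow")
  expect_equal(to_world(r$position, m), c(0.2, 0.6, 0), tolerance = 1e-12)
  # start distance d from a boundary edge, step 2d straight at it -> back home
  r <- propagate(surface_position(1, c(0.5, 0.1)), c(0, -0.2), m)
  expect_equal(r$position$local, c(0.5, 0.1), tolerance = 1e-12)
  # confinement makes the (crossable) diagonal reflective
  r <- propagate(surface_position(1, c(0.8, 0.1)), c(-0.6, 0.5), m,
                 confine = TRUE)
  expect_equal(nrow(r$crossings), 0)
})

test_that("unfolding preserves path length on a folded mesh", {
  fm <- folded_tri()
  set.seed(7)
  for (i in 1:500) {
    start <- surface_position(1, bary_to_local(fm, 1, runif(3) + 1e-3))
    disp <- runif(2, -0.5, 0.5)
    r <- propagate(start, disp, fm, record_path = TRUE)
    seg <- diff(r$path)
    plen <- sum(sqrt(rowSums(seg^2)))
    expect_equal(plen, sqrt(sum(disp^2)), tolerance = 1e-9)
  }
})

test_that("reflecting twice off the same edge reproduces the free endpoint", {
  m <- build_mesh(list(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0))))
  start <- surface_position(1, c(1, 1))
  # a step crossing the x-axis edge reflects; its mirror image continues free
  r <- propagate(start, c(0.5, -1.4), m)
  free <- c(1, 1) + c(0.5, -1.4)
  mirrored <- c(free[1], -free[2])
  expect_equal(r$position$local, mirrored, tolerance = 1e-12)
})

test_that("overly large steps trip the crossing budget", {
  m <- two_tri()
  expect_error(propagate(surface_position(1, c(0.5, 0.2)), c(200, 90), m,
                         max_crossings = 10),
               "max_crossings")
  expect_error(propagate(surface_position(1, c(0.5, 0.2)), c(0.1, 0), m,
                         max_crossings = 0), "max_crossings")
})

test_that("panel export writes one row per panel", {
  m <- two_tri()
  f <- tempfile(fileext = ".tsv")
  export_panels_tsv(m, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$surface, c("fast", "slow"))
  unlink(f)
})
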