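test_that("incidence matrix realizes the node-arc structure", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      rbind(c(1, 2, 3)))
  M <- build_incidence_matrix(tri)
  expect_equal(dim(M), c(3, 3))
  expect_true(all(Matrix::rowSums(M) == 0))
  expect_true(all(as.matrix(M) %in% c(-1, 0, 1)))

  tet <- tetra_mesh()
  Mt <- build_incidence_matrix(tet)
  expect_equal(dim(Mt), c(6, 4))
  expect_equal(Matrix::nnzero(Mt), 12)
  # brute-force unique undirected edge enumeration
  f <- tet$faces
  e <- unique(t(apply(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]), 1, sort)))
  expect_equal(nrow(e), 6)

  # isolated vertex keeps a zero column, no error
  iso <- surface_mesh(rbind(tri$vertices, c(5, 5, 5)), tri$faces)
  Mi <- build_incidence_matrix(iso)
  expect_equal(ncol(Mi), 4)
  expect_equal(sum(abs(Mi[, 4])), 0)

  empty <- surface_mesh(matrix(0, 1, 3), matrix(integer(0), 0, 3))
  expect_error(build_incidence_matrix(empty), "no edges")
})

test_that("incidence row sums vanish and edge counts match brute force", {
  for (m in list(icosphere(3, 2), tetra_mesh(), hemisphere_mesh(2, 6, 12))) {
    M <- build_incidence_matrix(m)
    expect_true(all(Matrix::rowSums(M) == 0))
    f <- m$faces
    e <- unique(t(apply(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]), 1, sort)))
    expect_equal(nrow(M), nrow(e))
  }
})

test_that("enclosed volume: analytic cases, invariances, scaling law", {
  expect_equal(enclosed_volume(box_mesh()), 0.001)

  ic <- icosphere(10, 4)
  expect_lt(abs(enclosed_volume(ic) - 4 / 3 * pi / 1000 * 1000) /
              (4 / 3 * pi), 0.005)

  tr <- ic
  tr$vertices <- sweep(tr$vertices, 2, c(100, 100, 100), "+")
  expect_lt(abs(enclosed_volume(tr) - enclosed_volume(ic)) /
              enclosed_volume(ic), 1e-9)

  for (s in c(0.5, 2, 10)) {
    sc <- ic
    sc$vertices <- ic$vertices * s
    expect_lt(abs(enclosed_volume(sc) - s^3 * enclosed_volume(ic)) /
                (s^3 * enclosed_volume(ic)), 1e-9)
  }

  expect_error(enclosed_volume(hemisphere_mesh(5)), "not closed")
})

test_that("surface area: analytic cases and degenerate triangles", {
  expect_equal(surface_area(box_mesh()), 6)
  expect_lt(abs(surface_area(icosphere(10, 4)) - 400 * pi) / (400 * pi), 0.005)
  degen <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                        rbind(c(1, 2, 3)))
  expect_equal(surface_area(degen), 0)
})

test_that("cap_boundary_loops closes open meshes with analytic volumes", {
  hm <- cap_boundary_loops(hemisphere_mesh(10, 32, 64))
  expect_length(boundary_loops(hm), 0)
  expect_lt(abs(enclosed_volume(hm) - 2 * pi / 3) / (2 * pi / 3), 0.01)

  closed <- icosphere(3, 2)
  expect_identical(cap_boundary_loops(closed), closed)

  cy <- cylinder_mesh(5, 20, 64, 4)
  expect_length(boundary_loops(cy), 2)
  cyc <- cap_boundary_loops(cy)
  expect_length(boundary_loops(cyc), 0)
  expect_lt(abs(enclosed_volume(cyc) - pi * 25 * 20 / 1000) /
              (pi * 25 * 20 / 1000), 0.01)

  # bowtie: two boundary loops meeting at one vertex is non-manifold
  bow <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                            c(-1, 0, 0), c(0, -1, 0)),
                      rbind(c(1, 2, 3), c(1, 4, 5)))
  expect_error(cap_boundary_loops(bow), "non-manifold")
})

test_that("clip_by_plane splits exactly and conserves volume", {
  ic <- icosphere(10, 3)
  vol <- enclosed_volume(ic)
  pl <- orifice_plane(c(0, 0, 0), c(0, 0, 1))
  lower <- enclosed_volume(clip_by_plane(ic, pl))
  upper <- enclosed_volume(clip_by_plane(ic, orifice_plane(c(0, 0, 0), c(0, 0, -1))))
  expect_lt(abs(lower - vol / 2) / (vol / 2), 1e-6)
  expect_lt(abs(lower + upper - vol) / vol, 1e-9)

  # oblique plane: conservation only
  pl2 <- orifice_plane(c(1, -2, 3), c(1, 2, 0.5))
  kept <- enclosed_volume(clip_by_plane(ic, pl2))
  rest <- enclosed_volume(clip_by_plane(ic, orifice_plane(pl2$point, -pl2$normal)))
  expect_lt(abs(kept + rest - vol) / vol, 1e-9)

  # plane not touching the mesh, mesh on the kept side
  far <- clip_by_plane(ic, orifice_plane(c(0, 0, 50), c(0, 0, 1)))
  expect_equal(enclosed_volume(far), vol)

  # cube cut at 1/4 height
  cb <- box_mesh(c(0, 0, 0), c(10, 10, 10))
  q <- clip_by_plane(cb, orifice_plane(c(0, 0, 2.5), c(0, 0, 1)))
  expect_equal(enclosed_volume(q), 0.25)

  # empty kept side
  none <- clip_by_plane(cb, orifice_plane(c(0, 0, -5), c(0, 0, 1)))
  expect_equal(enclosed_volume(none), 0)

  # vessel-cut emulation: open cut with one boundary ring per plane
  cut <- slice_surface(ic, orifice_plane(c(0, 0, 6), c(0, 0, 1)))
  expect_length(boundary_loops(cut), 1)
  expect_lt(abs(enclosed_volume(cap_boundary_loops(cut)) -
                  enclosed_volume(clip_by_plane(ic, orifice_plane(c(0, 0, 6), c(0, 0, 1))))),
            1e-9)
})

test_that("extract_region shares the ostium ring and writes back", {
  ph <- generate_phantom_cycle(coarse_phantom_spec())
  laa <- extract_region(ph$source, ph$labels, "LAA")
  # the open boundary of the LAA submesh is exactly the ostium loop
  bl <- boundary_loops(laa$mesh)
  expect_length(bl, 1)
  expect_setequal(laa$vertex_map[bl[[1]]],
                  which(ph$labels == REGION[["LAA_OSTIUM"]]))

  # chambers and LAA share the ostium ring, so their areas overlap there
  ch <- extract_region(ph$source, ph$labels, "chambers")
  expect_gte(surface_area(ch$mesh) + surface_area(laa$mesh),
             surface_area(ph$source))

  # unmodified round trip is bit-identical
  out <- write_back(ph$source$vertices, laa$mesh$vertices, laa$vertex_map)
  expect_identical(out, ph$source$vertices)

  expect_error(extract_region(ph$source, ph$labels, "NOPE"), "unknown region")
})
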