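# soma plus explicit dendrite nodes (type 3), rows: id type x y z r parent
swc_df <- function(...) {
  m <- rbind(...)
  tree <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                     x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                     parent = as.integer(m[, 7]))
  v1sync:::validate_swc(tree)
}

# one primary that bifurcates once: two terminals of order 2, length 30
tree_bifurc <- swc_df(
  c(1, 1, 0, 0, 0, 5, -1),
  c(2, 3, 10, 0, 0, 1, 1),
  c(3, 3, 10, 10, 0, 1, 2),
  c(4, 3, 10, -10, 0, 1, 2))

# two unbranched primaries, lengths 60 and 40
tree_two <- swc_df(
  c(1, 1, 0, 0, 0, 5, -1),
  c(2, 3, 60, 0, 0, 1, 1),
  c(3, 3, 0, 40, 0, 1, 1))

test_that("SWC files round-trip and tolerate arbitrary line order", {
  t1 <- make_morphology(seed = 3)
  p <- tempfile(fileext = ".swc")
  write_swc(t1, p)
  t2 <- read_swc(p)
  # node order within the file is arbitrary; compare by id
  reord <- function(tr) { tr <- tr[order(tr$id), ]; rownames(tr) <- NULL; tr }
  expect_equal(reord(t2), reord(t1), ignore_attr = TRUE, tolerance = 1e-5)

  lines <- readLines(p)
  body <- lines[-1]
  shuffled <- c(lines[1], body[rev(seq_along(body))])
  p2 <- tempfile(fileext = ".swc")
  writeLines(shuffled, p2)
  t3 <- read_swc(p2)
  m_a <- branch_metrics(t2)
  m_b <- branch_metrics(t3)
  expect_equal(m_b$total_length_um, m_a$total_length_um)
  expect_equal(sort(m_b$terminal_orders), sort(m_a$terminal_orders))
})

test_that("malformed SWC input is rejected with a reason", {
  good <- data.frame(id = 1:2, type = c(1L, 3L), x = c(0, 1), y = 0, z = 0,
                     radius = 1, parent = c(-1L, 1L))
  dup <- good; dup$id <- c(1L, 1L)
  expect_error(v1sync:::validate_swc(dup), "duplicate")
  two_roots <- good; two_roots$parent <- c(-1L, -1L)
  expect_error(v1sync:::validate_swc(two_roots), "one root")
  orphan <- good; orphan$parent <- c(-1L, 9L)
  expect_error(v1sync:::validate_swc(orphan), "orphan")
  cyc <- data.frame(id = 1:3, type = c(1L, 3L, 3L), x = 0:2, y = 0, z = 0,
                    radius = 1, parent = c(-1L, 3L, 2L))
  expect_error(v1sync:::validate_swc(cyc), "cycle")

  p <- tempfile(fileext = ".swc")
  writeLines(c("# header", "1 1 0 0 0 5 -1", "2 3 1 0 0"), p)
  expect_error(read_swc(p), "line 3")
})

test_that("branch metrics and DC match hand calculations", {
  m <- branch_metrics(tree_bifurc)
  expect_equal(m$n_primary, 1)
  expect_equal(m$n_nodes, 1)
  expect_equal(m$n_ends, 2)
  expect_equal(m$total_length_um, 30)
  expect_equal(sort(m$terminal_orders), c(2, 2))
  # DC = (2 + 2 + 2 ends) * 30 / 1 primary
  expect_equal(dendritic_complexity(m), 180)

  m2 <- branch_metrics(tree_two)
  expect_equal(m2$n_primary, 2)
  expect_equal(m2$n_nodes, 0)
  expect_equal(sort(m2$terminal_orders), c(1, 1))
  expect_equal(m2$mean_length_um, 50)
  # DC = (1 + 1 + 2 ends) * 100 / 2 primaries
  expect_equal(dendritic_complexity(tree_two), 200)

  # minimal tree: one primary stub
  stub <- swc_df(c(1, 1, 0, 0, 0, 5, -1), c(2, 3, 0, 0, 12, 1, 1))
  expect_equal(dendritic_complexity(stub), (1 + 1) * 12)
})

test_that("axon nodes are excluded and DC scales with length", {
  with_axon <- swc_df(
    c(1, 1, 0, 0, 0, 5, -1),
    c(2, 3, 60, 0, 0, 1, 1),
    c(3, 3, 0, 40, 0, 1, 1),
    c(4, 2, 0, 0, -80, 1, 1),   # axon (type 2)
    c(5, 2, 0, 0, -160, 1, 4))
  expect_equal(dendritic_complexity(with_axon),
               dendritic_complexity(tree_two))

  doubled <- tree_two
  doubled$x <- doubled$x * 2
  doubled$y <- doubled$y * 2
  doubled$z <- doubled$z * 2
  expect_equal(dendritic_complexity(doubled),
               2 * dendritic_complexity(tree_two))
})

test_that("random trees agree with the recursive traversal oracle", {
  for (s in 1:100) {
    tr <- make_morphology(n_primary = sample(2:6, 1),
                          branch_prob = runif(1, 0, 0.6), seed = s)
    m <- branch_metrics(tr)
    o <- oracle_branch_metrics(tr)
    expect_equal(m$n_primary, o$n_primary)
    expect_equal(m$n_nodes, o$n_nodes)
    expect_equal(m$n_ends, o$n_ends)
    expect_equal(m$total_length_um, o$total_length_um)
    expect_equal(sort(m$terminal_orders), o$terminal_orders)
  }
})

test_that("normalization turns the reference group into unit means", {
  trees <- lapply(1:6, function(s) make_morphology(seed = s))
  tab <- morpho_table(trees)
  expect_equal(nrow(tab), 6)
  norm <- normalize_to_reference(tab, tab)
  expect_equal(unname(colMeans(norm)), rep(1, ncol(tab)))
  expect_error(normalize_to_reference(tab, c(dc = 0)), "zero")
})
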