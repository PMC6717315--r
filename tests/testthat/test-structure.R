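test_that("radius of gyration matches closed forms", {
  # coincident points
  expect_equal(radius_of_gyration(matrix(5, 4, 3)), 0)
  # two points at distance d -> d/2
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(3, 4, 0))), 2.5)
  # discrete rod of 11 collinear points spaced 1 sigma: sqrt((11^2-1)/12)
  rod <- cbind(0:10, 0, 0)
  expect_equal(radius_of_gyration(rod), sqrt(120 / 12))
  expect_error(radius_of_gyration(matrix(0, 0, 3)), "at least one")
})

# minimal hand-built ensemble around arbitrary coordinate snapshots
coords_ensemble <- function(chain, coords_list) {
  coords <- array(0, c(chain$n_beads, 3, length(coords_list)))
  for (k in seq_along(coords_list)) coords[, , k] <- coords_list[[k]]
  structure(list(chain = chain, coords = coords,
                 time = seq_along(coords_list),
                 replica = rep(1L, length(coords_list)),
                 kinetic = rep(0, length(coords_list)),
                 potential = rep(0, length(coords_list)),
                 config = sim_config(), seed = 0L),
            class = "ensemble")
}

test_that("a frozen straight rod scales with exponent exactly 1", {
  ch <- build_dna_chain(80)
  rod <- cbind(cumsum(c(0, ch$bonds$r0)), 0, 0)
  ens <- coords_ensemble(ch, list(rod))
  rgc <- rg_vs_length(ens, c(5, 10, 20, 40, 80))
  # Rg of an L-bead rod: sqrt((L^2-1)/12); exponent -> 1 for large L
  expect_equal(rgc$Rg_mean, sqrt(((c(5, 10, 20, 40, 80))^2 - 1) / 12))
  slope_tail <- diff(log(rgc$Rg_mean))[4] / diff(log(rgc$L))[4]
  expect_equal(slope_tail, 1, tolerance = 0.01)
})

test_that("rg_vs_length is invariant under rigid transforms", {
  ch <- build_dna_chain(40)
  set.seed(3)
  conf <- matrix(rnorm(120), 40, 3)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ens1 <- coords_ensemble(ch, list(conf))
  ens2 <- coords_ensemble(ch, list(conf %*% R + rep(c(5, -2, 9), each = 40)))
  L <- c(5, 10, 20, 40)
  expect_equal(rg_vs_length(ens1, L)$Rg_mean, rg_vs_length(ens2, L)$Rg_mean,
               tolerance = 1e-10)
})

test_that("local Rg/lambda bookkeeping conserves window composition", {
  ch <- build_chain(generate_regular_positions(22, 10))
  conf <- init_conformation(ch, "straight")
  ens <- coords_ensemble(ch, list(conf))
  prof <- local_rg_profile(ens, L = 11)
  expect_equal(prof$Nn + prof$Nd, rep(11, nrow(prof)))
  expect_equal(prof$lambda, sqrt(prof$Nd + 4 * prof$Nn))
  expect_equal(nrow(prof), ch$n_beads - 10)
  # windows with more nucleosomes have larger contour -> larger lambda
  expect_true(all(diff(prof$lambda[order(prof$Nn)]) >= 0))
})

test_that("linker context statistics classify by midpoint and strand", {
  # regular fiber, no genes: single category with a point-mass histogram
  pos <- generate_regular_positions(22, 20)
  ls <- linker_stats(pos)
  expect_named(ls, "all")
  expect_true(all(ls$all$lengths == 22))
  expect_equal(ls$all$mean_bp, 22)
  expect_equal(unname(ls$all$fractions), c(0, 1, 0))

  # hand-built positions: one long NDR linker inside a known gene layout
  starts <- c(0, 150, 300, 700, 850)        # linkers: 3,3,253,3 bp
  pos2 <- nuc_positions(starts, 1100, footprint_bp = 147)
  genes <- gene_annotation(data.frame(
    start = c(0), end = c(1100), strand = "+", active = TRUE))
  ls2 <- linker_stats(pos2, genes)
  # 253-bp linker is excluded (> 200 bp artifact rule)
  expect_equal(ls2$all$n, 3)
  expect_equal(unname(ls2$all$fractions), c(1, 0, 0))
  expect_equal(ls2$gene_body$n, 3)
  expect_equal(ls2$nongenic$n, 0)

  # fractions sum to 1 with binomial SEs
  spec <- default_linker_spec()
  pos3 <- generate_positions(spec, 2e5, seed = 2)
  g3 <- generate_toy_genes(2e5, 30, seed = 3)
  ls3 <- linker_stats(pos3, g3)
  for (cat in names(ls3)) {
    s <- ls3[[cat]]
    if (s$n > 0) {
      expect_equal(sum(s$fractions), 1, tolerance = 1e-9)
      expect_equal(unname(s$se), unname(sqrt(s$fractions *
        (1 - s$fractions) / s$n)), tolerance = 1e-12)
    }
  }
  # genome-wide fractions track the spec (all sampled linkers are <= 200)
  expect_lt(abs(ls3$all$fractions[1] - 0.25), 0.04)
  expect_lt(abs(ls3$all$fractions[3] - 0.12), 0.04)
})

test_that("boundary linkers at planted NDRs are longer than average", {
  # plant NDR-like linkers at known indices
  spec <- linker_spec(list(list(weight = 1, kind = "point", value = 20L)))
  base <- sample_linker_lengths(spec, 40, seed = 1)
  ndr_at <- c(10, 25)
  base[ndr_at] <- 150L
  starts <- cumsum(c(0, 147 + base))
  pos <- nuc_positions(starts, max(starts) + 147)
  b <- boundary_set(ndr_at)
  ls <- linker_stats(pos, boundaries = b)
  expect_equal(ls$boundary$n, 2)
  expect_equal(ls$boundary$mean_bp, 150)
  expect_gt(ls$boundary$mean_bp, ls$all$mean_bp)
})

test_that("upstream windows respect strand", {
  # nucleosomes with linker midpoints at known bp
  starts <- seq(0, by = 200, length.out = 11)  # linkers 53 bp, mids at 173.5+200k
  pos <- nuc_positions(starts, 2200, footprint_bp = 147)
  # + strand gene [1000, 2100): upstream window [500, 1000)
  gp <- gene_annotation(data.frame(start = 1000, end = 2100, strand = "+",
                                   active = TRUE))
  lp <- linker_stats(pos, gp)
  mids <- (starts[-11] + 147 + starts[-1]) / 2
  expect_equal(lp$upstream500$n, sum(mids >= 500 & mids < 1000))
  # - strand gene [0, 1100): upstream window [1100, 1600)
  gm <- gene_annotation(data.frame(start = 0, end = 1100, strand = "-",
                                   active = TRUE))
  lm <- linker_stats(pos, gm)
  expect_equal(lm$upstream500$n, sum(mids >= 1100 & mids < 1600))
})
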