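field_of <- function(values) sensitivity_field(values, grid68)

test_that("MMS selects all loci and gates event eligibility at 8 dB", {
  set.seed(1)
  v <- random_field(grid68)
  sel <- select_mms(field_of(v), grid68)
  expect_equal(length(sel$locus_ids), 68)
  expect_equal(length(sel$eligible_event_ids), sum(v >= 8))
  zero <- select_mms(field_of(rep(0L, 68)), grid68)
  expect_length(zero$eligible_event_ids, 0)
})

test_that("ESS is the seeing edge of the scotoma", {
  # no scotoma anywhere -> empty with flag
  sel <- select_ess(field_of(rep(20L, 68)), grid68)
  expect_length(sel$locus_ids, 0)
  expect_true("no-scotoma" %in% sel$flags)
  # a single interior -1: its 8 Chebyshev neighbours
  v <- rep(20L, 68)
  id11 <- grid68$loci$id[grid68$loci$x == 1 & grid68$loci$y == 1]
  v[id11] <- -1L
  sel <- select_ess(field_of(v), grid68)
  expect_setequal(sel$locus_ids, grid68$adjacency[[as.character(id11)]])
  # all -1: the scotomatous loci themselves are never edge loci
  sel <- select_ess(field_of(rep(-1L, 68)), grid68)
  expect_length(sel$locus_ids, 0)
})

test_that("FTP ranking counts 7 dB drops with -1 as an arithmetic value", {
  v <- rep(20L, 68)
  rk <- rank_ftp(field_of(v), grid68)
  expect_true(all(rk$proportion == 0))        # uniform field: no drops
  expect_equal(nrow(rk), 68)
  # loci below 8 dB are unranked
  v[3] <- 7L
  rk <- rank_ftp(field_of(v), grid68)
  expect_false(3 %in% rk$id)
  # hand case: 10 dB locus with orthogonal neighbours {2, 3, 15, 20} ->
  # drops of 8 and 7 dB, so 2 of 4
  g4 <- build_grid(adjacency_scheme = "orthogonal4")
  id11 <- g4$loci$id[g4$loci$x == 1 & g4$loci$y == 1]
  nb4 <- g4$adjacency[[as.character(id11)]]
  v <- rep(20L, 68)
  v[id11] <- 10L
  v[nb4] <- c(2L, 3L, 15L, 20L)
  rk4 <- rank_ftp(sensitivity_field(v, g4), g4)
  expect_equal(rk4$proportion[rk4$id == id11], 0.5)
  # same locus under chebyshev8: the 2 drops dilute among 8 neighbours
  nb8 <- grid68$adjacency[[as.character(id11)]]
  v[setdiff(nb8, nb4)] <- 20L
  rk8 <- rank_ftp(field_of(v), grid68)
  expect_equal(rk8$proportion[rk8$id == id11], 2 / 8)
  # a -1 neighbour of an 8 dB locus counts: 8 - (-1) = 9 >= 7
  v <- rep(20L, 68)
  v[id11] <- 8L
  v[nb8[1]] <- -1L
  rk <- rank_ftp(field_of(v), grid68)
  expect_equal(rk$proportion[rk$id == id11], 1 / 8)
})

test_that("raising the drop threshold never enlarges a proportion", {
  set.seed(2)
  for (rep in 1:20) {
    f <- field_of(random_field(grid68))
    r7 <- rank_ftp(f, grid68, drop_db = 7)
    r9 <- rank_ftp(f, grid68, drop_db = 9)
    shared <- intersect(r7$id, r9$id)
    expect_true(all(r9$proportion[match(shared, r9$id)] <=
                      r7$proportion[match(shared, r7$id)]))
  }
})

test_that("mFTP takes full-proportion loci then whole tied tiers to >= 5", {
  mk <- function(ids, props, base = 20L) {
    data.frame(id = ids, baseline_db = base, n_neighbors = 4L,
               n_drop = round(props * 4), proportion = props)
  }
  # six loci at proportion 1 -> exactly those six
  sel <- select_mftp(mk(1:6, rep(1, 6)))
  expect_setequal(sel$locus_ids, 1:6)
  # 3 at 1.0, 4 at 0.5 -> all 7 (whole tier included)
  sel <- select_mftp(mk(1:10, c(rep(1, 3), rep(0.5, 4), rep(0, 3))))
  expect_setequal(sel$locus_ids, 1:7)
  # zero-proportion tiers are never selectable
  sel <- select_mftp(mk(1:8, rep(0, 8)))
  expect_length(sel$locus_ids, 0)
  expect_true("ineligible-for-event" %in% sel$flags)
  # fewer than 5 positive-proportion loci: all selected, flagged
  sel <- select_mftp(mk(1:4, c(1, 1, 0.5, 0.25)))
  expect_setequal(sel$locus_ids, 1:4)
  expect_true("ineligible-for-event" %in% sel$flags)
})

test_that("HRS selects ring-transected squares and excludes baseline -1 from trend", {
  # circle of radius 3: hand-checkable membership via corner distances
  ring <- polygonize_ring(radius = 3)
  v <- rep(15L, 68)
  sel <- select_hrs(field_of(v), grid68, ring)
  oracle <- grid68$loci$id[vapply(seq_len(68), function(i) {
    s <- as.numeric(grid68$squares[i, c("xmin", "xmax", "ymin", "ymax")])
    oracle_circle_transects(s, c(0, 0), 3)
  }, logical(1))]
  expect_setequal(sel$locus_ids, oracle)
  # baseline -1 inside the selection: kept, but trend-ineligible
  v[sel$locus_ids[1]] <- -1L
  sel2 <- select_hrs(field_of(v), grid68, ring)
  expect_true(sel$locus_ids[1] %in% sel2$locus_ids)
  expect_false(sel2$trend_eligible[sel2$locus_ids == sel$locus_ids[1]])
  # ring beyond the grid: empty with flag
  far <- polygonize_ring(radius = 30)
  sel3 <- select_hrs(field_of(v), grid68, far)
  expect_length(sel3$locus_ids, 0)
  expect_true("no-hrs-loci" %in% sel3$flags)
})

test_that("selection means follow each metric's arithmetic rules", {
  uni <- field_of(rep(12L, 68))
  expect_equal(evaluate_selection(select_mms(uni, grid68), uni), 12)
  # -1 enters the MMS mean arithmetically
  v <- rep(0L, 68); v[5] <- -1L
  f <- field_of(v)
  expect_equal(evaluate_selection(select_mms(f, grid68), f), -1 / 68)
  # HRS excludes baseline -1 loci from the mean
  ring <- polygonize_ring(radius = 3)
  v <- rep(15L, 68)
  sel0 <- select_hrs(field_of(v), grid68, ring)
  v[sel0$locus_ids[1]] <- -1L
  f <- field_of(v)
  sel <- select_hrs(f, grid68, ring)
  expect_equal(evaluate_selection(sel, f), 15)
  # empty effective set -> NA sentinel, never 0
  empty <- select_ess(field_of(rep(20L, 68)), grid68)
  expect_true(is.na(evaluate_selection(empty, uni)))
})

test_that("selections match brute-force oracles on random fields", {
  set.seed(99)
  for (rep in 1:40) {
    v <- random_field(grid68)
    f <- field_of(v)
    expect_setequal(select_ess(f, grid68)$locus_ids, oracle_ess(v, grid68))
    expect_setequal(select_mftp(rank_ftp(f, grid68))$locus_ids,
                    oracle_mftp(v, grid68))
    ctr <- runif(2, -2, 2); r <- runif(1, 1, 8)
    ring <- polygonize_ring(center = ctr, radius = r)
    hrs <- select_hrs(f, grid68, ring)$locus_ids
    oracle <- grid68$loci$id[vapply(seq_len(68), function(i) {
      s <- as.numeric(grid68$squares[i, c("xmin", "xmax", "ymin", "ymax")])
      oracle_transects(s, ring$vertices)
    }, logical(1))]
    expect_setequal(hrs, oracle)
  }
})

test_that("selection is deterministic and mFTP reaches 5 when possible", {
  set.seed(4)
  for (rep in 1:20) {
    v <- random_field(grid68)
    f <- field_of(v)
    a <- select_mftp(rank_ftp(f, grid68))
    b <- select_mftp(rank_ftp(f, grid68))
    expect_identical(a$locus_ids, b$locus_ids)
    rk <- rank_ftp(f, grid68)
    if (sum(rk$proportion > 0) >= 5) expect_gte(length(a$locus_ids), 5)
    # every ESS locus is non-scotomatous with a scotomatous neighbour
    ess <- select_ess(f, grid68)
    for (i in ess$locus_ids) {
      expect_true(v[i] != -1)
      expect_true(any(v[grid68$adjacency[[as.character(i)]]] == -1))
    }
  }
})
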