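sp2 <- search_space(c(0, 0), c(1, 1))

test_that("population initialization respects bounds and the seed", {
  withr::with_seed(1, pop <- fho_init_population(sp2, 10))
  expect_equal(dim(pop), c(10, 2))
  expect_true(all(pop >= 0 & pop <= 1))
  withr::with_seed(1, pop2 <- fho_init_population(sp2, 10))
  expect_identical(pop, pop2)
  narrow <- search_space(c(0), c(1e-9))
  withr::with_seed(2, p <- fho_init_population(narrow, 5))
  expect_true(all(p >= 0 & p <= 1e-9))
  expect_error(fho_init_population(sp2, 3), class = "nutriclass_config_error")
  expect_error(search_space(c(0, 1), c(1, 1)), class = "nutriclass_config_error")
})

test_that("hawk selection takes the best candidates with a Gaussian count", {
  sel <- fho_select_hawks(fitness = c(5, 1, 4, 2, 9, 3, 8, 7, 6, 10),
                          hawk_count_cap = 0.2, g = 1.0)
  expect_length(sel$hawks, 2)                 # round(1 * 10 * 0.2)
  expect_equal(sel$hawks, c(2, 4))            # the two lowest fitnesses
  expect_length(fho_select_hawks(rep(1, 10), 0.2, g = 0)$hawks, 1)  # floor 1
  expect_length(fho_select_hawks(rep(1, 10), 0.5, g = 50)$hawks, 5) # cap n/2
  expect_equal(fho_select_hawks(c(3, 1, 2), 0.2, g = 0.1)$hawks, 2)
  expect_error(fho_select_hawks(c(1, NA, 3)), class = "nutriclass_state_error")
})

test_that("territories are claimed greedily by distance with a balanced quota", {
  # 3-4-5 triangle: single hawk claims the prey at distance 5
  pos <- rbind(c(0, 0), c(3, 4))
  terr <- fho_assign_territories(1L, 2L, pos)
  expect_equal(terr[["1"]], 2L)
  # 2 hawks, 4 prey, symmetric: two each, nearest first
  pos <- rbind(c(0, 0), c(10, 0),               # hawks
               c(1, 0), c(2, 0), c(9, 0), c(8, 0))  # prey
  terr <- fho_assign_territories(c(1L, 2L), 3:6, pos)
  expect_setequal(terr[["1"]], c(3L, 4L))
  expect_setequal(terr[["2"]], c(5L, 6L))
  # 1 hawk claims everything
  terr <- fho_assign_territories(1L, 3:6, pos)
  expect_setequal(terr[["1"]], 3:6)
  # every prey in exactly one territory
  expect_equal(sort(unname(unlist(terr))), 3:6)
  # empty prey set
  expect_equal(fho_assign_territories(c(1L, 2L), integer(0), pos)[["1"]],
               integer(0))
})

test_that("hawk update follows the attraction/repulsion rule and clamps", {
  big <- search_space(c(-10, -10), c(10, 10))
  expect_equal(fho_update_hawk(c(2, 3), c(0, 0), c(1, 1), big, rand = c(0, 0)),
               c(2, 3))
  expect_equal(fho_update_hawk(c(1, 1), c(1, 1), c(1, 1), big,
                               rand = c(0.5, 0.5)), c(1, 1))
  expect_equal(fho_update_hawk(c(0, 0), c(2, 0), c(0, 0), big,
                               rand = c(0.5, 0.3)), c(1, 0))
  clamped <- fho_update_hawk(c(9, 9), c(9, 9), c(-9, -9), sp2, rand = c(1, 1))
  expect_true(all(clamped >= sp2$lower & clamped <= sp2$upper))
})

test_that("safe places are prey means with documented fallbacks", {
  expect_equal(fho_safe_place_within(rbind(c(0, 0), c(2, 2)), c(9, 9)), c(1, 1))
  expect_equal(fho_safe_place_within(rbind(c(3, 4)), c(9, 9)), c(3, 4))
  expect_equal(fho_safe_place_within(NULL, c(9, 9)), c(9, 9))
  expect_equal(fho_safe_place_global(matrix(numeric(0), 0, 2), c(7, 7)),
               c(7, 7))
})

test_that("prey update evaluates both movement rules and clamps", {
  big <- search_space(c(-10, -10), c(10, 10))
  expect_equal(fho_update_prey(c(1, 2), c(0, 0), c(0, 0), c(0, 0), c(0, 0),
                               big, within = TRUE, rand = c(0, 0)), c(1, 2))
  # symmetric cancellation in the within-territory move
  expect_equal(fho_update_prey(c(0, 0), c(1, 1), c(9, 9), c(1, 1), c(9, 9),
                               big, within = TRUE, rand = c(0.7, 0.7)), c(0, 0))
  # outside move toward another hawk
  expect_equal(fho_update_prey(c(1, 0), c(9, 9), c(3, 0), c(9, 9), c(1, 0),
                               big, within = FALSE, rand = c(0.5, 0.5)), c(2, 0))
  out <- fho_update_prey(c(0.9, 0.9), c(1, 1), c(1, 1), c(0, 0), c(0, 0),
                         sp2, within = TRUE, rand = c(1, 1))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("the optimizer finds the 1-D quadratic optimum", {
  sp1 <- search_space(0, 4)
  fit <- fho_minimize(function(x) (x - 2)^2, sp1,
                      fho_config(pop_size = 20, max_iters = 60, seed = 3))
  expect_lt(abs(fit$par - 2), 0.05)
})

test_that("a constant objective yields a constant history", {
  fit <- fho_minimize(function(x) 7, sp2,
                      fho_config(pop_size = 8, max_iters = 10, seed = 1))
  expect_equal(fit$history, rep(7, 10))
  expect_true(all(fit$par >= 0 & fit$par <= 1))
})

test_that("elitist history is monotone and seeded runs are bit-identical", {
  obj <- function(x) sum((x - 0.3)^2) + 0.1 * sum(sin(20 * x)^2)
  f1 <- fho_minimize(obj, sp2, fho_config(pop_size = 12, max_iters = 40, seed = 5))
  f2 <- fho_minimize(obj, sp2, fho_config(pop_size = 12, max_iters = 40, seed = 5))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$par, f2$par)
  expect_true(all(diff(f1$history) <= 0))
  expect_length(f1$history, 40)
  f3 <- fho_minimize(obj, sp2, fho_config(pop_size = 12, max_iters = 40, seed = 6))
  expect_false(identical(f1$history, f3$history))
})

test_that("non-finite objectives raise an optimization error naming the position", {
  expect_error(
    fho_minimize(function(x) NaN, sp2,
                 fho_config(pop_size = 8, max_iters = 2, seed = 1)),
    regexp = "non-finite", class = "nutriclass_optim_error")
})

test_that("fho_fit methods expose the convergence trace", {
  fit <- fho_minimize(function(x) sum(x^2), sp2,
                      fho_config(pop_size = 8, max_iters = 5, seed = 2))
  td <- tidy(fit)
  expect_equal(names(td), c("iteration", "best_fitness"))
  expect_equal(nrow(td), 5)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_equal(glance(fit)$best_fitness, fit$value)
})
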