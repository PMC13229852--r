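# On-chip memory model and parameter counting.

test_that("axonal buffering memory is n_in * 2^B_d", {
  expect_equal(mem_axonal(memory_spec(n_in = 116, B_d = 5)), 3712)
  expect_equal(mem_axonal(memory_spec(n_in = 1, B_d = 0)), 1)
  s1 <- memory_spec(n_in = 37); s2 <- memory_spec(n_in = 74)
  expect_equal(mem_axonal(s2), 2 * mem_axonal(s1))
})

test_that("synaptic buffering adds the delayed-current ring buffers", {
  expect_equal(mem_synaptic(memory_spec(116, 128, B_d = 5, B_v = 16)), 69248)
  expect_equal(mem_synaptic(memory_spec(n_hidden = 0)),
               mem_axonal(memory_spec(n_hidden = 0)))
  s <- memory_spec(B_v = 1)
  expect_equal(mem_synaptic(s), s$n_in * 2^s$B_d + s$n_hidden * 2^s$B_d)
})

test_that("trace memory is the surrogate look-up table per hidden neuron", {
  expect_equal(mem_trace(memory_spec(n_hidden = 128, k = 12, B_v = 16)),
               24576)
  expect_equal(mem_trace(memory_spec(k = 0)), 0)
  expect_equal(mem_trace(memory_spec(n_hidden = 64, k = 6, B_v = 8)),
               64 * 6 * 8)
})

test_that("memory terms are nondecreasing in every field", {
  base <- list(n_in = 50, n_hidden = 40, n_out = 10, B_w = 6, B_d = 4,
               B_v = 12, k = 8)
  for (f in names(base)) {
    lo <- do.call(memory_spec, base)
    hi_args <- base; hi_args[[f]] <- base[[f]] + 2
    hi <- do.call(memory_spec, hi_args)
    expect_gte(mem_axonal(hi), mem_axonal(lo))
    expect_gte(mem_synaptic(hi), mem_synaptic(lo))
    expect_gte(mem_trace(hi), mem_trace(lo))
    expect_gte(memory_footprint(hi, "synaptic")$total,
               memory_footprint(lo, "synaptic")$total)
  }
})

test_that("parameter counts reproduce the 116-128-20 architecture column", {
  expect_equal(param_count(116, 128, 20), 17408)
  expect_equal(param_count(116, 128, 20, flavor_in = "synaptic"), 32256)
  expect_equal(param_count(116, 128, 20, flavor_in = "axonal"), 17524)
  # recurrent accounting: input + recurrent delay counts add up
  both <- param_count(116, 128, 20, flavor_in = "synaptic",
                      flavor_rec = "synaptic", recurrent = TRUE)
  rec_only <- param_count(116, 128, 20, flavor_rec = "synaptic",
                          recurrent = TRUE)
  in_only <- param_count(116, 128, 20, flavor_in = "synaptic",
                         recurrent = TRUE)
  none <- param_count(116, 128, 20, recurrent = TRUE)
  expect_equal(both - none, (rec_only - none) + (in_only - none))
  # sparsity scales the synaptic terms
  expect_equal(param_count(116, 128, 20, flavor_in = "synaptic",
                           density_in = 0.2),
               round(116 * 128 * 0.2) * 2 + 128 * 20)
})

test_that("footprint decomposes into parameters, state and learning", {
  spec <- memory_spec()
  fp <- memory_footprint(spec, "weights_only")
  expect_equal(fp$parameters, (116 * 128 + 128 * 20) * 8)
  expect_equal(fp$state, (128 + 20) * 16)
  expect_equal(fp$learning, 0)
  expect_equal(fp$total, fp$parameters + fp$state)
  fa <- memory_footprint(spec, "axonal")
  expect_equal(fa$learning, mem_axonal(spec) + mem_trace(spec))
  expect_equal(fa$parameters - fp$parameters, 116 * 5)  # 580 delay bits
  fs <- memory_footprint(spec, "synaptic")
  expect_equal(fs$learning, mem_synaptic(spec) + mem_trace(spec))
})

test_that("minimum sparsity to fit the weights-only budget is reported", {
  spec <- memory_spec()
  fa <- memory_footprint(spec, "axonal")
  fs <- memory_footprint(spec, "synaptic")
  expect_true(fa$min_sparsity_to_fit > 0 && fa$min_sparsity_to_fit < 1)
  expect_gt(fs$min_sparsity_to_fit, fa$min_sparsity_to_fit)
  # at that density the footprint indeed fits the budget
  budget <- memory_footprint(spec, "weights_only")$total
  for (fl in c("axonal", "synaptic")) {
    ms <- memory_footprint(spec, fl)$min_sparsity_to_fit
    # synapse-count rounding can cost at most one synapse's worth of bits
    expect_lte(memory_footprint(spec, fl, density = 1 - ms)$total,
               budget + 13)
  }
  sweep <- memory_sweep(spec, "synaptic", densities = c(0.1, 0.5, 1))
  expect_equal(nrow(sweep), 3)
  expect_true(sweep$fits_weights_only_budget[1])
  expect_false(sweep$fits_weights_only_budget[3])
})
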