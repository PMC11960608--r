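# Shared fixtures, built once per test run. Expensive objects are cached in
# this environment so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# desk-scale phantom used by most unit tests (the acceptance tests use the
# full default 48 x 48 x 96 grid)
small_phantom <- function() fixture("small_phantom", function()
  build_phantom(shape = c(24, 24, 48)))

small_noisefree_late <- function() fixture("small_nf_late", function()
  simulate_dynamic(small_phantom(), feng_input(), late_schedule(40, 4, 5)))

small_noisy_late <- function() fixture("small_noisy_late", function()
  simulate_dynamic(small_phantom(), feng_input(), late_schedule(40, 4, 5),
                   noise_scale = 1, seed = 11))

# full default grid, where thin structures (aorta, marrow) are resolved
default_phantom <- function() fixture("default_phantom", function()
  build_phantom())

default_noisefree_late <- function() fixture("default_nf_late", function()
  simulate_dynamic(default_phantom(), feng_input(), late_schedule(40, 4, 5)))

expect_rel_equal <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol * pmax(abs(expected), 1e-300)),
              label = sprintf("max rel err %.3g vs tol %.3g",
                              max(abs(object - expected) /
                                    pmax(abs(expected), 1e-300)), tol))
}
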