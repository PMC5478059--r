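# Shared metacommunities, built once per test run (construction is
# deterministic, so caching does not couple tests).
.fixtures <- new.env(parent = emptyenv())

mc_spatial <- function() {
  if (is.null(.fixtures$mcs))
    .fixtures$mcs <- logseries_metacommunity(5.5e6, alpha = 272)
  .fixtures$mcs
}

mc_low <- function() {
  if (is.null(.fixtures$mclow))
    .fixtures$mclow <- logseries_metacommunity(20191600511, S = 4582)
  .fixtures$mclow
}

tiny_meta <- function() {
  if (is.null(.fixtures$tiny))
    .fixtures$tiny <- logseries_metacommunity(1e4, S = 50)
  .fixtures$tiny
}

# hand-made two-species pool with equal abundances (p = 1/2, 1/2)
two_species_meta <- function() {
  structure(list(N = 10, S = 2L, alpha = 1, x = 10 / 11,
                 abundance = c(5, 5), species = c("spA", "spB")),
            class = "logseries_meta")
}
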