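# Shared fixtures: all synthetic, built in code.

# closed-form A(t) for the irreversible second-order reaction A + B -> C
# with unequal initial concentrations (oracle for single-step kinetics)
analytic_second_order <- function(A0, B0, k, t) {
  stopifnot(abs(A0 - B0) > 1e-12)
  A0 * (B0 - A0) / (B0 * exp((B0 - A0) * k * t) - A0)
}

# single-site DAR2 distribution: every heavy chain carries exactly one
# reactive cysteine -> the whole system is one A + B -> C reaction
single_site_dar2 <- function() {
  cysteine_distribution(c("0" = 0, "1" = 1, "2" = 0), max_heavy = 2)
}

# minimal design preset for fast synthetic-data tests
tiny_preset <- function(spec, rates, distribution, conditions, roles,
                        name = "tiny", payload_id = "X") {
  structure(list(spec = spec, rates = rates, distribution = distribution,
                 payload_id = payload_id, conditions = conditions,
                 roles = roles, name = name),
            class = "dataset_preset")
}

# sum over (chain, nc) groups of a hidden trajectory; rows = times
group_totals <- function(sim) {
  tab <- sim$structure$tab
  groups <- paste(tab$chain, tab$nc)
  t(apply(sim$hidden, 1, function(row) tapply(row, groups, sum)))
}

# bound-drug equivalents (sum of d * concentration) per time point
bound_drug <- function(sim) {
  as.numeric(sim$hidden %*% sim$structure$tab$d)
}

# mean reactive sites per mAb of a distribution (2 chains of each kind)
sites_per_mab <- function(dist) {
  h <- sum(as.integer(names(dist$heavy_fractions)) * dist$heavy_fractions)
  l <- sum(as.integer(names(dist$light_fractions)) * dist$light_fractions)
  2 * h + 2 * l
}

table2_dar8_rates <- c(1.220, 1.853, 5.117, 2.312)
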