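# shared objects; cheap to build, computed once per test run
fx <- ppi_fixtures()
qualifying_conversion <- stoich(c("atp", "pi", "adp", "ppi"), c(-1, -1, 1, 1))

support_keys <- function(solutions) {
  sort(vapply(solutions, function(s) paste(s$support, collapse = ","), character(1)))
}
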