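# Small configurations assembled through the parser (exercising the dialect
# on the way) for reaction kinetics tests.

square_tris <- function(L) {
  c(sprintf("tri 0 0 0 %g 0 0 %g %g 0", L, L, L),
    sprintf("tri 0 0 0 %g %g 0 0 %g 0", L, L, L))
}

# well-mixed A + B -> C on an L x L plane, 500 + 500 molecules
.surfdiff_test_pair_config <- function(L = 3) {
  parse_config(c(
    "species A B C",
    "difc A 1", "difc B 1", "difc C 1",
    "surface plane", square_tris(L),
    "reaction pair A + B -> C 0.05",
    "mol 500 A surface=all random",
    "mol 500 B surface=all random",
    "time_start 0", "time_stop 0.8", "time_step 0.001",
    "output_interval 40",
    "output counts counts.tsv"))
}

# immobile first-order decay A -> B
.surfdiff_test_decay_config <- function(n = 2000, k = 1) {
  parse_config(c(
    "species A B",
    "difc A 0", "difc B 0",
    "surface plane", square_tris(1),
    sprintf("reaction decay A -> B %g", k),
    sprintf("mol %d A surface=all random", n),
    "time_start 0", "time_stop 1", "time_step 0.001",
    "output_interval 1000",
    "output counts counts.tsv"))
}
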