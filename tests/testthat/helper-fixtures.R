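# Small fixtures shared across test files. Everything is generated in code.

tiny_gene <- function() make_uniform_gene(10L, 1000L)

# one 4-hr hormone-on window
one_induction <- function(duration_min = 240, inhibitor = "none",
                          nup98 = FALSE) {
  induction_protocol(data.frame(duration_min = duration_min, hormone = TRUE,
                                nup98_depleted = nup98,
                                inhibitor = inhibitor))
}

# spot table builder: one row per spot
spot_row <- function(cell, compartment, intensity, id = NULL) {
  data.frame(cell_id = cell, spot_id = if (is.null(id)) seq_along(cell) else id,
             compartment = compartment, intensity_cu = intensity)
}
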