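# hand-built containers for unit tests

makeNrDb <- function(ecs, orgs, maps) {
  nrIds <- sprintf("nr%06d", seq_along(ecs))
  prov <- do.call(rbind, lapply(seq_along(ecs), function(k)
    data.frame(nr_id = nrIds[k], organism = orgs[[k]], map_id = maps[[k]],
               stringsAsFactors = FALSE)))
  new("NRESSDatabase",
      sequences = data.frame(nr_id = nrIds, ecs = ecs,
                             stringsAsFactors = FALSE),
      provenance = prov)
}

makeTable <- function(i, j, score, n = length(unique(c(i, j)))) {
  new("AlignmentTable",
      records = data.frame(i = i, j = j, score = score,
                           stringsAsFactors = FALSE),
      settings = list(matrix_mode = "uniform", gap = 1.0,
                      keep_ceiling = 1.0, n = n,
                      n_pairs = n * (n - 1) / 2))
}

# minimal hand-written KGML document
toyKGML <- function() {
  paste(
    '<?xml version="1.0"?>',
    '<pathway name="path:tst00010" org="tst" number="00010" title="toy">',
    '  <entry id="1" name="cpd:C1" type="compound"/>',
    '  <entry id="2" name="cpd:C9" type="compound" link="path:map00020"/>',
    '  <entry id="3" name="ec:1.1.1.1" type="enzyme" reaction="rn:R1"/>',
    '  <entry id="4" name="ec:2.7.1.11 ec:4.1.2.13" type="enzyme" reaction="rn:R2"/>',
    '  <reaction id="11" name="rn:R1" type="irreversible">',
    '    <substrate id="1" name="cpd:C1"/>',
    '    <product id="5" name="cpd:C2"/>',
    '  </reaction>',
    '  <reaction id="12" name="rn:R2" type="reversible">',
    '    <substrate id="5" name="cpd:C2"/>',
    '    <product id="6" name="cpd:C3"/>',
    '  </reaction>',
    '  <reaction id="13" name="rn:R3" type="irreversible">',
    '    <substrate id="6" name="cpd:C3"/>',
    '    <product id="7" name="cpd:C4"/>',
    '  </reaction>',
    '</pathway>', sep = "\n")
}
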