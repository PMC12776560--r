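# Shared fixture builders. Everything is generated in code; no files ship
# with the tests.

# Hand-rolled PDB text with full control over atom names, altlocs and
# extra records, independent of write_c1_chain().
pdb_text <- function(atoms, extra = character()) {
  recs <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00",
            a$record, i, a$name, a$alt, a$res, a$chain, a$resno, a$ins,
            a$x, a$y, a$z)
  }, character(1))
  paste(c(recs, extra, "END", ""), collapse = "\n")
}

atom_row <- function(name, res, resno, x, y, z, chain = "A", alt = " ",
                     ins = " ", record = "ATOM") {
  data.frame(record = record, name = name, alt = alt, res = res,
             chain = chain, resno = resno, ins = ins, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

# A rigid motion that is definitely not axis-aligned.
test_transform <- function(angle = 37, axis = c(1, 2, 3) / sqrt(14),
                           shift = c(5, -2, 1)) {
  a <- angle * pi / 180
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  rigid_transform(R, shift)
}

random_chain_pair <- function(i, nrange = 4:8) {
  set.seed(9000 + i)
  n <- sample(nrange, 1)
  m <- sample(nrange, 1)
  list(a = generate_chain(n, "coil", seed = 2 * i + 1),
       b = generate_chain(m, "coil", seed = 2 * i + 2))
}

# TM value of a chain pair recomputed from a tm_result's own components,
# used to check internal consistency.
recompute_tm <- function(res, model, reference) {
  tm_fixed(model, reference, res$alignment,
           transform = res$superposition, lref = res$lref, d0 = res$d0)
}
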