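#' @keywords internal
"_PACKAGE"

## Static element data (CODATA/IUPAC). Masses in Da, abundances as fractions.
## Column 1 of each isotope matrix is the lightest (monoisotopic) isotope.

.ms_elements <- c("C", "H", "O", "N", "P", "S", "F", "Cl", "Na", "K")

.ms_isotopes <- list(
  C  = list(mass = c(12.0, 13.0033548378),
            abundance = c(0.9893, 0.0107)),
  H  = list(mass = c(1.00782503207, 2.0141017778),
            abundance = c(0.999885, 0.000115)),
  O  = list(mass = c(15.9949146196, 16.9991317, 17.9991610),
            abundance = c(0.99757, 0.00038, 0.00205)),
  N  = list(mass = c(14.0030740048, 15.0001088982),
            abundance = c(0.99636, 0.00364)),
  P  = list(mass = 30.97376163, abundance = 1),
  S  = list(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  F  = list(mass = 18.99840322, abundance = 1),
  Cl = list(mass = c(34.96885268, 36.96590259),
            abundance = c(0.7576, 0.2424)),
  Na = list(mass = 22.9897692809, abundance = 1),
  K  = list(mass = c(38.96370668, 39.96399848, 40.96182576),
            abundance = c(0.932581, 0.000117, 0.067302))
)

.ms_monoisotopic <- vapply(.ms_isotopes, function(x) x$mass[1], numeric(1))

.ms_electron_mass <- 0.00054857990907
.ms_proton_mass <- .ms_monoisotopic[["H"]] - .ms_electron_mass

## Valences used for ring-plus-double-bond equivalents:
## RDBE = 1 + C + N/2 + P/2 - (H + F + Cl + Na + K)/2
.ms_rdbe_weight <- c(C = 1, H = -0.5, O = 0, N = 0.5, P = 0.5, S = 0,
                     F = -0.5, Cl = -0.5, Na = -0.5, K = -0.5)
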