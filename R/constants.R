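# Physical constants used throughout the simulator.
#
# Isotope masses (Da) and abundances: IUPAC/CIAAW values for the elements that
# occur in lipid-like formulas. Each element maps to a matrix with columns
# `mass` and `abundance`, sorted by mass; abundances sum to 1.

.isotope_table <- list(
  C = cbind(mass = c(12.0000000, 13.00335483507),
            abundance = c(0.9893, 0.0107)),
  H = cbind(mass = c(1.00782503224, 2.01410177812),
            abundance = c(0.999885, 0.000115)),
  N = cbind(mass = c(14.00307400446, 15.00010889894),
            abundance = c(0.99636, 0.00364)),
  O = cbind(mass = c(15.99491461960, 16.99913175664, 17.99915961284),
            abundance = c(0.99757, 0.00038, 0.00205)),
  P = cbind(mass = 30.97376199842, abundance = 1.0),
  S = cbind(mass = c(31.97207117440, 32.97145890980, 33.96786701000,
                     35.96708071000),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Na = cbind(mass = 22.98976928200, abundance = 1.0),
  K = cbind(mass = c(38.96370648640, 39.96399817000, 40.96182525790),
            abundance = c(0.932581, 0.000117, 0.067302)),
  Cl = cbind(mass = c(34.96885268000, 36.96590260200),
             abundance = c(0.7576, 0.2424))
)

# Singly-charged cation masses added to the neutral monoisotopic mass
# (electron mass already subtracted).
.adduct_masses <- c(H = 1.007276, Na = 22.989218, K = 38.963158)

# FT-ICR constants: the unperturbed cyclotron relation f [Hz] =
# .cyclotron_constant * B0 [T] / (m/z) and the resolution prefactor in
# m/dm = .resolution_constant * z * B0 * T_aqn / m.
.cyclotron_constant  <- 1.535611e7
.resolution_constant <- 1.274e7

# A default panel of 30 lipid-like chemical formulas (phosphatidylcholines,
# ethanolamines, sphingomyelins, ceramides, hexosylceramides, ...) used by the
# MSI simulator when the caller does not supply a formula list.
.default_formulas <- c(
  "C40H80NO8P", "C42H82NO8P", "C44H84NO8P", "C46H84NO8P", "C42H78NO8P",
  "C39H76NO8P", "C41H78NO8P", "C43H80NO8P", "C41H74NO8P", "C45H86NO8P",
  "C39H79N2O6P", "C41H83N2O6P", "C47H93N2O6P", "C45H91N2O6P", "C43H85N2O6P",
  "C34H67NO3",  "C36H71NO3",  "C40H79NO3",  "C42H81NO3",  "C38H75NO3",
  "C40H77NO8",  "C42H81NO8",  "C46H87NO8",  "C44H83NO8",  "C48H93NO8",
  "C27H46O",    "C43H76O13P2","C37H71O8P",  "C39H73O8P",  "C45H78NO10P"
)
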