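# Elemental property tables used by the descriptor engine.
#
# Masses are standard atomic weights. Van der Waals volumes are derived from
# Bondi radii (4/3*pi*r^3); autocorrelation descriptors use them scaled
# relative to carbon. McGowan increments are the published characteristic
# volume contributions (cm^3/mol), with 6.56 subtracted per bond. Rb0 are the
# bond radii used by the Labute-style surface-area approximation.

.element_table <- local({
  df <- data.frame(
    element = c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I"),
    mass    = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998, 28.085, 30.974,
                32.06, 35.45, 79.904, 126.904),
    bondi_r = c(1.20, 1.92, 1.70, 1.55, 1.52, 1.47, 2.10, 1.80, 1.80, 1.75,
                1.85, 1.98),
    mcgowan = c(8.71, 18.32, 16.35, 14.39, 12.43, 10.48, 26.83, 24.87, 22.91,
                20.95, 26.21, 34.53),
    rb0     = c(0.33, 0.84, 0.77, 0.70, 0.66, 0.611, 1.11, 0.89, 1.04, 0.997,
                1.167, 1.387),
    stringsAsFactors = FALSE
  )
  df$vdw_vol <- (4 / 3) * pi * df$bondi_r^3
  rownames(df) <- df$element
  df
})

# default valence lists for implicit-hydrogen assignment (neutral atoms)
.element_valences <- list(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = c(3, 5),
  S = c(2, 4, 6), Cl = 1, Br = 1, I = 1
)

.element_prop <- function(elements, prop) {
  tab <- .element_table
  unknown <- setdiff(unique(elements), rownames(tab))
  if (length(unknown) > 0L) {
    stop("no tabulated ", prop, " for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  tab[elements, prop]
}
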