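# internal unit helpers: user-facing lengths are um, times s, permeabilities
# cm/s, concentrations nM; derived compartment constants are cm-based

um_to_cm <- function(x) x * 1e-4

# Parse a scalar quantity that may be numeric (assumed already in `target`
# units) or a "value unit" string, e.g. "1.8 mm", "300 s", "5 min".
parse_quantity <- function(x, target = c("um", "s", "nM", "cm/s"),
                           field = deparse(substitute(x))) {
  target <- match.arg(target)
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x) || length(x) != 1)
    stop(sprintf("field '%s': expected a number or 'value unit' string", field))
  m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+)\\s*([^ ]*)\\s*$", x))[[1]]
  if (length(m) != 3 || is.na(suppressWarnings(as.numeric(m[2]))))
    stop(sprintf("field '%s': cannot parse quantity '%s'", field, x))
  val <- as.numeric(m[2]); unit <- m[3]
  if (unit == "") return(val)
  conv <- switch(target,
    um = c(nm = 1e-3, um = 1, "µm" = 1, "μm" = 1, mm = 1e3,
           cm = 1e4, m = 1e6, A = 1e-4, angstrom = 1e-4),
    s = c(s = 1, sec = 1, min = 60, h = 3600, hr = 3600),
    nM = c(pM = 1e-3, nM = 1, uM = 1e3, "µM" = 1e3, mM = 1e6),
    "cm/s" = c("cm/s" = 1, "um/s" = 1e-4, "mm/s" = 0.1))
  if (!unit %in% names(conv))
    stop(sprintf("field '%s': unknown unit '%s' (target %s)", field, unit, target))
  val * conv[[unit]]
}
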