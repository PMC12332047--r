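#' Read and write simulation configurations
#'
#' Configurations are flat YAML files with three sections (`device`,
#' `circuit`, `drive`); every quantity is stored as a `{value, unit}` pair so
#' files are self-describing.  Units follow the package's dimensionless
#' scheme: lengths in gap units `L`, time in circuit units `tau`, resistance
#' in load units `R_ext`, temperature in energy units (`k_B = 1`).
#'
#' @param device a [device_params()].
#' @param circuit a [circuit_params()].
#' @param drive a [drive_protocol()].
#' @param path file path of the YAML configuration.
#' @return `read_config()` returns a list with elements `device`, `circuit`,
#'   `drive`; `write_config()` returns `path` invisibly.
#' @export
write_config <- function(device, circuit, drive, path) {
  qty <- function(value, unit) list(value = value, unit = unit)
  dev <- list(
    R_t = qty(device$R_t, "R_ext"),
    lambda = qty(device$lambda, "L"),
    L = qty(device$L, "L"),
    eta = qty(device$eta, "force*tau/L"),
    q = qty(device$q, "charge"),
    q_T = qty(device$q_T, "force/(temperature/L)"),
    C_th = qty(device$C_th, "energy/temperature"),
    kappa = qty(device$kappa, "1/tau"),
    k_B = qty(device$k_B, "energy/temperature"),
    n_particles = qty(device$n_particles, "count"),
    field_sign = qty(device$field_sign, "sign"),
    potential = c(list(kind = device$potential$kind,
                       well_position = qty(device$potential$well_position,
                                           "L")),
                  if (device$potential$kind == "polynomial") {
                    list(coefficients = qty(device$potential$coefficients,
                                            "energy/L^k"))
                  } else {
                    list(x = qty(device$potential$x, "L"),
                         U = qty(device$potential$U, "energy"))
                  }))
  circ <- list(R_ext = qty(circuit$R_ext, "R_ext"),
               C = qty(circuit$C, "tau/R_ext"),
               D_V = qty(circuit$D_V, "voltage^2*tau"))
  drv <- list(voltage = lapply(drive$voltage, identity),
              temperature = lapply(drive$temperature, identity))
  yaml::write_yaml(list(device = dev, circuit = circ, drive = drv), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop_tn("configuration file '%s' not found", path,
            class = "tn_config_error")
  }
  raw <- yaml::read_yaml(path)
  need <- setdiff(c("device", "circuit", "drive"), names(raw))
  if (length(need)) {
    stop_tn("configuration is missing section(s): %s",
            paste(need, collapse = ", "), class = "tn_config_error")
  }
  val <- function(node) {
    if (is.list(node) && !is.null(node$value)) node$value else node
  }
  dv <- raw$device
  pot_node <- dv$potential
  potential <- if (identical(pot_node$kind, "polynomial")) {
    potential_spec("polynomial",
                   coefficients = unlist(val(pot_node$coefficients)),
                   well_position = val(pot_node$well_position))
  } else {
    potential_spec("tabulated", x = unlist(val(pot_node$x)),
                   U = unlist(val(pot_node$U)),
                   well_position = val(pot_node$well_position))
  }
  device <- device_params(R_t = val(dv$R_t), lambda = val(dv$lambda),
                          L = val(dv$L), eta = val(dv$eta), q = val(dv$q),
                          q_T = val(dv$q_T), C_th = val(dv$C_th),
                          kappa = val(dv$kappa), k_B = val(dv$k_B),
                          n_particles = val(dv$n_particles),
                          potential = potential,
                          field_sign = val(dv$field_sign))
  circuit <- circuit_params(R_ext = val(raw$circuit$R_ext),
                            C = val(raw$circuit$C),
                            D_V = val(raw$circuit$D_V))
  drive <- drive_protocol(voltage = lapply(raw$drive$voltage, identity),
                          temperature = lapply(raw$drive$temperature,
                                               identity))
  list(device = device, circuit = circuit, drive = drive)
}
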