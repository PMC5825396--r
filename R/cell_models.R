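# Cell-model objects and the two reduced fixture cell types.
#
# A cell_model bundles an identifier, a full named parameter vector (in the
# exact order the compiled right-hand side expects), named initial state,
# and capability flags.  The first 13 parameters are the maximal-rate
# transport parameters, one per canonical pathway key.

# parameter order; must match the enum in src/fixture.cpp
.param_names <- c(
  "GNa", "GK1", "GKr", "GKs", "Gto", "GCaL", "KNCX", "KNaK",
  "GpCa", "GbNa", "GbCa", "KRyR", "KSERCA",
  "Nao", "Cao", "Ko", "Nai", "Ki",
  "conv", "vsr", "Kmup", "kleak", "Bmax", "Kdbuf",
  "tau_f_scale", "tau_xr_scale"
)

.state_names <- c("V", "h", "d", "f", "r", "xr", "xs", "Cai", "CaSR")

new_cell_model <- function(id, params, state0, paced, spontaneous) {
  stopifnot(identical(names(params), .param_names),
            identical(names(state0), .state_names))
  keys <- transport_pathways()
  if (any(!is.finite(params)) || any(params[keys] < 0)) {
    stop("invalid model parameters")
  }
  structure(
    list(id = id, params = params, state0 = state0,
         capabilities = c(paced = paced, spontaneous = spontaneous)),
    class = "cell_model")
}

#' Reduced fixture cell models
#'
#' Two reduced cardiac myocyte models sharing one formulation and all 13
#' ion-transport pathways:
#' \describe{
#'   \item{`"adult"`}{an adult-ventricular-like cell: stable resting
#'     potential near -85 mV, stimulated AP with APD90 in the 200-350 ms
#'     range at 1 Hz pacing.}
#'   \item{`"ipsc"`}{an iPSC-cardiomyocyte-like cell: small inward
#'     rectifier current and larger background Na+ current give a
#'     depolarised maximum diastolic potential and spontaneous
#'     automaticity at roughly 0.5-1.5 Hz.}
#' }
#' Both models keep intracellular Na+/K+ fixed so Ca2+ cycling is the only
#' slow process and steady state is reached within a few beats.  The full
#' equations are described in the package vignette.
#'
#' @param kind `"adult"` or `"ipsc"`.
#' @return A `cell_model` object.
#' @examples
#' adult <- fixture_model("adult")
#' adult$params[transport_pathways()]
#' @export
fixture_model <- function(kind = c("adult", "ipsc")) {
  kind <- match.arg(kind)
  if (kind == "adult") {
    params <- c(
      GNa = 3.5, GK1 = 0.65, GKr = 0.18, GKs = 0.08, Gto = 0.18,
      GCaL = 4, KNCX = 2500, KNaK = 3, GpCa = 0.05,
      GbNa = 6e-4, GbCa = 5e-4, KRyR = 0.02, KSERCA = 0.005,
      Nao = 151, Cao = 1.8, Ko = 5.4, Nai = 7.2, Ki = 140,
      conv = 1.5e-5, vsr = 15, Kmup = 6e-4, kleak = 5e-5,
      Bmax = 0.024, Kdbuf = 0.00238,
      tau_f_scale = 1, tau_xr_scale = 1)
    state0 <- c(V = -87.06, h = 0.9324, d = 7.1e-6, f = 0.9998, r = 0.9999,
                xr = 0.125, xs = 0.05925, Cai = 6.32e-5, CaSR = 1.16)
    new_cell_model("fixture_adult", params, state0,
                   paced = TRUE, spontaneous = FALSE)
  } else {
    params <- c(
      GNa = 1.5, GK1 = 0.02, GKr = 0.12, GKs = 0.05, Gto = 0.03,
      GCaL = 3, KNCX = 2000, KNaK = 2, GpCa = 0.04,
      GbNa = 7.5e-3, GbCa = 4e-4, KRyR = 0.012, KSERCA = 0.003,
      Nao = 151, Cao = 1.8, Ko = 5.4, Nai = 10, Ki = 140,
      conv = 1.5e-5, vsr = 15, Kmup = 6e-4, kleak = 5e-5,
      Bmax = 0.024, Kdbuf = 0.00238,
      tau_f_scale = 1.3, tau_xr_scale = 1)
    state0 <- c(V = -56.73, h = 0.1231, d = 7.45e-4, f = 0.9896, r = 0.9764,
                xr = 0.1556, xs = 0.08436, Cai = 1.02e-4, CaSR = 1.447)
    new_cell_model("fixture_ipsc", params, state0,
                   paced = TRUE, spontaneous = TRUE)
  }
}

#' Make both fixture models
#'
#' @return List with elements `adult` (paced) and `ipsc` (spontaneous).
#' @export
make_fixture_models <- function() {
  list(adult = fixture_model("adult"), ipsc = fixture_model("ipsc"))
}

#' Override extracellular ion concentrations
#'
#' Extracellular concentrations are plain parameters of a `cell_model`
#' and can be changed without touching the rest of the model.  Overrides
#' are applied as an instantaneous solution change at t = 0.
#'
#' @param model A `cell_model`.
#' @param Nao,Cao,Ko New concentrations in mM; `NULL` keeps the current
#'   value.
#' @return Modified `cell_model`.
#' @export
set_extracellular <- function(model, Nao = NULL, Cao = NULL, Ko = NULL) {
  stopifnot(inherits(model, "cell_model"))
  for (nm in c("Nao", "Cao", "Ko")) {
    v <- switch(nm, Nao = Nao, Cao = Cao, Ko = Ko)
    if (!is.null(v)) {
      if (!is.finite(v) || v <= 0) stop(nm, " must be positive")
      model$params[[nm]] <- v
    }
  }
  model
}

#' @export
print.cell_model <- function(x, ...) {
  cat("<cell_model> ", x$id, "\n", sep = "")
  caps <- names(x$capabilities)[x$capabilities]
  cat("  capabilities: ", paste(caps, collapse = ", "), "\n", sep = "")
  cat("  extracellular (mM): Nao=", x$params[["Nao"]],
      " Cao=", x$params[["Cao"]], " Ko=", x$params[["Ko"]], "\n", sep = "")
  tp <- signif(x$params[transport_pathways()], 3)
  cat("  transport parameters:\n")
  print(tp)
  invisible(x)
}
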