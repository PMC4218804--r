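# Independent second-solver oracle: scipy.optimize.linprog (HiGHS) via the
# command-line python.  The oracle receives raw model data (S, bounds,
# objective) and formulates its own LPs - including the FVA objective floor
# as an inequality row - so no formulation code is shared with the package.

lp_oracle_script <- '
import json, sys
import numpy as np
from scipy.optimize import linprog

inp = json.load(open(sys.argv[1]))
out = []
for mdl in inp["models"]:
    S = np.array(mdl["S"], dtype=float)
    if S.ndim == 1:
        S = S.reshape(1, -1)
    lb = np.array(mdl["lb"], dtype=float)
    ub = np.array(mdl["ub"], dtype=float)
    c = np.array(mdl["obj"], dtype=float)
    frac = mdl["fraction"]
    n = S.shape[1]
    bounds = list(zip(lb, ub))
    beq = np.zeros(S.shape[0])
    r = linprog(-c, A_eq=S, b_eq=beq, bounds=bounds, method="highs")
    if r.status != 0:
        out.append({"status": int(r.status)})
        continue
    fstar = -r.fun
    A_ub = -c.reshape(1, -1)
    b_ub = np.array([-frac * fstar])
    mins, maxs = [], []
    for j in range(n):
        e = np.zeros(n); e[j] = 1.0
        lo = linprog(e, A_eq=S, b_eq=beq, A_ub=A_ub, b_ub=b_ub,
                     bounds=bounds, method="highs")
        hi = linprog(-e, A_eq=S, b_eq=beq, A_ub=A_ub, b_ub=b_ub,
                     bounds=bounds, method="highs")
        mins.append(lo.fun)
        maxs.append(-hi.fun)
    out.append({"status": 0, "f": fstar, "fva_min": mins, "fva_max": maxs})
json.dump(out, open(sys.argv[2], "w"))
'

# models: list of list(S = matrix, lb, ub, obj); returns per model either
# list(status != 0) or list(status = 0, f, fva_min, fva_max)
oracle_fba_fva <- function(models, fraction = 1.0) {
  script <- tempfile(fileext = ".py")
  writeLines(lp_oracle_script, script)
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  payload <- list(models = lapply(models, function(m) {
    list(S = m$S, lb = m$lb, ub = m$ub, obj = m$obj, fraction = fraction)
  }))
  jsonlite::write_json(payload, infile, digits = NA, auto_unbox = TRUE)
  status <- system2("python", c(script, infile, outfile),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(outfile)) {
    stop("LP oracle subprocess failed: ", paste(status, collapse = "\n"))
  }
  jsonlite::read_json(outfile, simplifyVector = TRUE,
                      simplifyDataFrame = FALSE)
}

model_to_oracle_input <- function(model) {
  list(S = as.matrix(model$S),
       lb = model$reactions$lower_bound,
       ub = model$reactions$upper_bound,
       obj = model$reactions$objective_coefficient)
}
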