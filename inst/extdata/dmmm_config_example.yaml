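# Example DMMM run configuration. Paths are relative to this file.
scenario: fusing
t_final: 33
dt: 0.1
models:
  fermenter: toy_fermenter.json        # written by make-fixtures.R
  acetogen: toy_acetogen.json
  hybrid_fermenter: hybrid_fermenter.json   # written by build-hybrid.R
  hybrid_acetogen: hybrid_acetogen.json
curves:
  glc: glucose_mmol_l.csv              # columns time_h,value
  fru: fructose_mmol_l.csv
growth:
  init_frac_A: 0.1
  init_total: 1.0e11
  f: 1.09e-12
  mu_A: 0.5                            # used when no OD tables given
  mu_B: 0.2
schedule:
  - {start: 0,    end: 10.4, organism: A, fraction: 0.56, consumes: ""}
  - {start: 0,    end: 10.4, organism: B, fraction: 0.05, consumes: ""}
  - {start: 10.4, end: 21,   organism: A, fraction: 0.35, consumes: "but,lac"}
  - {start: 10.4, end: 21,   organism: B, fraction: 1,    consumes: ""}
  - {start: 21,   end: 33,   organism: A, fraction: 0.35, consumes: "but,lac"}
  - {start: 21,   end: 33,   organism: B, fraction: 1,    consumes: "acetone"}
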