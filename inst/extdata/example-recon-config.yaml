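# Example configuration for the tomo-opt CLI.
#
#   tomo-opt simulate inst/extdata/example-recon-config.yaml
#   tomo-opt recon    inst/extdata/example-recon-config.yaml
#
# (the same file carries both blocks; unused blocks are ignored)

phantom:
  kind: steel_wire_like
  size: 64               # grid size (alias for 'n', which YAML 1.1 mangles)
  v_max: 0.05            # peak optical depth ~1.5 on this grid
  seed: 1

geometry:
  beam_type: parallel2D
  golden_angles: 90      # or an explicit `angles:` list in degrees
  pixel_num_h: 64

noise:
  type: poisson
  I0: 10000.0
  seed: 7

output:
  format: hdf5
  path: sino.h5

input:                   # consumed by `recon`
  format: hdf5
  path: sino.h5

algorithm:
  name: pdhg-tv          # fbp | cgls | sirt | fista-tv | pdhg-tv | gd-stv
  alpha: 0.1
  iterations: 500
  eval_interval: 50

history_csv: history.csv
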