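# Example holopm pipeline configuration.
# A 3-hour simulated deployment of a desk-scale (128 x 128 px) sensor;
# eta is the device's collection efficiency scaled by the imaged-area
# ratio of the simulated sensor to the 10-megapixel device sensor.
optics:
  sensor_shape: [128, 128]
  wavelength_nm: 528.0
  bandwidth_nm: 30.0
  pixel_pitch_um: 1.67
  z_um: 1000.0
film:
  thickness0_nm: 110.0
  decay_time_h: 48.0
noise:
  read_noise_sigma: 1.0
  bit_depth: 8
thresholds: auto
calibration: beads
eta: 3.129e-07
Q_Lpm: 4.5
rho_kgm3: 1050.0
bin_edges_nm: [50, 100, 200, 500, 1000, 2500]
seed: 5
out_dir: holopm_out
simulate:
  duration_h: 3
  concentration_profile: [6, 9, 7]
  size:
    type: lognormal
    median_nm: 600.0
    gsd: 1.6
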