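# Low-contrast phantom + base-dose acquisition, as read by read_phantom_config()
phantom:
  kind: catphan_lowcontrast
  background_hu: 63.4
  disk_contrast_hu: 10
  disk_diameter_mm: 10
  field_of_view_mm: 250
  grid_size: 256
acquisition:
  mas_per_rot: 456
  reference_mas: 456
  rotation_ms: 280
  window_ms: 70
  sigma_ref_hu: 8.475
  kernel_sigma_mm: 0.62
  recon_flavor: FBP_like
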