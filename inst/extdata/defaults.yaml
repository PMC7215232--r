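# precoolr default physical constants and study conditions.
# One entry per symbol; units annotated. Values without a literature source
# are package calibrations documented in the methods vignette.
schema_version: 1
air:
  rho_a:    {value: 1.293,     units: kg m-3,   note: dry air at 0 C}
  mu_a:     {value: 1.72e-5,   units: Pa s,     note: dry air at 0 C}
  cp_a:     {value: 1006.0,    units: J kg-1 K-1, note: dry air at 0 C}
  k_a:      {value: 0.0243,    units: W m-1 K-1, note: dry air at 0 C}
  D_wv:     {value: 2.2e-5,    units: m2 s-1,   note: water vapor in air at 0 C}
  M_a:      {value: 0.028966,  units: kg mol-1}
  M_h2o:    {value: 0.018015,  units: kg mol-1}
  p_atm:    {value: 101325.0,  units: Pa}
fruit:
  k_p:      {value: 0.57,      units: W m-1 K-1, note: strawberry flesh}
  cp_p:     {value: 3950.0,    units: J kg-1 K-1}
  rho_p:    {value: 800.0,     units: kg m-3}
  d:        {value: 0.03,      units: m,        note: equivalent sphere diameter}
  vpl:      {value: 0.99,      units: dimensionless, note: vapor-pressure lowering of fresh tissue}
  kg_skin:  {value: 5.5e-8,    units: s m-1,    note: strawberry cuticle permeance class}
environment:
  t_air_in: {value: 1.0,       units: C,        note: cold-room supply}
  rh:       {value: 0.8,       units: fraction}
  t_product_0: {value: 16.0,   units: C,        note: field heat at harvest}
  specific_airflow: {value: 0.4, units: L s-1 kg-1}
correlation:
  sh_coeff:  {value: 0.522,    units: dimensionless, note: Sh = 2 + c Re^0.53 Sc^0.33, as printed}
  re_exp:    {value: 0.53,     units: dimensionless}
  sc_exp:    {value: 0.33,     units: dimensionless}
geometry:
  package_mass:        {value: 1.0,     units: kg,  note: product mass per package}
  package_surface_area: {value: 0.08333, units: m2, note: calibrated so base vent set gives 28.2% opening}
  zone_cross_area:     {value: 0.00835, units: m2,  note: calibrated so default IPAS gives in-package Re ~ 54}
  zone_air_volume:     {value: 6.25e-4, units: m3,  note: free air per half-package at ~50% porosity}
flow:
  cd_default: {value: 0.61,    units: dimensionless, note: sharp-edged orifice discharge coefficient}
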