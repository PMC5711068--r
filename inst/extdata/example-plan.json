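{"plan_id":"example-2beam","beams":[
 {"gantry_deg":40,"beam_mu":100,"segments":[
  {"left_positions":[2,3,3,2],"right_positions":[-2,-3,-3,-2],"mu_weight":60},
  {"left_positions":[1,2,2,1],"right_positions":[-1,-2,-2,-1],"mu_weight":40}]},
 {"gantry_deg":180,"beam_mu":80,"segments":[
  {"left_positions":[2.5,2.5,2.5,2.5],"right_positions":[-2.5,-2.5,-2.5,-2.5],"mu_weight":80}]}]}
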