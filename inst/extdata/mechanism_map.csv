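mechanism,class
cut_pierce,penetrating
firearm,penetrating
fall,blunt
motor_vehicle_traffic,blunt
other_land_transport,blunt
other_transport,blunt
pedal_cyclist,blunt
pedestrian,blunt
struck_by_against,blunt
machinery,blunt
drowning,excluded
fire_flame,excluded
poisoning,excluded
suffocation,excluded
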