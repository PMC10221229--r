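kind,rule,enabled,description
A,carbonyl_oxygen,TRUE,Oxygen double-bonded to a carbon (aldehyde / ketone / ester / lactone carbonyl); acceptor placed on the oxygen nucleus
A,ether_ester_oxygen,TRUE,Divalent non-aromatic oxygen bonded to two heavy atoms (ether / ester / acetal bridge); acceptor on the oxygen nucleus
A,hydroxyl_oxygen,TRUE,Oxygen bonded to one heavy atom and carrying a hydrogen (alcohol / phenol); acceptor on the oxygen nucleus
A,nitrogen_acceptor,TRUE,Trivalent nitrogen with a lone pair; amide and nitro nitrogens excluded; acceptor on the nitrogen nucleus
H,carbon_group,TRUE,Connected group of two or more non-polar carbons (no bond to any heteroatom and not aromatic); hydrophobe at the heavy-atom centroid
H,terminal_methyl,TRUE,Isolated terminal non-polar carbon such as an acetate methyl; hydrophobe on the carbon nucleus
R,aromatic_ring,TRUE,Planar conjugated 5- or 6-membered ring; ring feature at the centroid with the unit plane normal
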