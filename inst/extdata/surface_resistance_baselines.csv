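# Baseline surface-resistance table for the big-leaf resistance scheme.
# Wesely (1989)-style seasonal baselines (s m-1) for the 11 dry-deposition
# land categories used by this package; 9999 marks a blocked pathway
# (read as infinite resistance). ri: minimum bulk stomatal resistance;
# rlu: upper-canopy cuticular; rac: in-canopy aerodynamic; rgs_*: ground
# (soil/litter) for the SO2 and O3 reference gases; rcl_*: lower-canopy
# surfaces for the SO2 and O3 reference gases.
# Seasons: 1 midsummer lush, 2 autumn unharvested, 3 late autumn frost
# (no snow), 4 winter snow (unused in the dry snow-free scope), 5 spring.
season,category_id,ri,rlu,rac,rgs_so2,rgs_o3,rcl_so2,rcl_o3
1,1,9999,9999,100,400,300,9999,9999
1,2,60,2000,200,150,150,2000,1000
1,3,120,2000,100,350,200,2000,1000
1,4,70,2000,2000,500,200,2000,1000
1,5,130,2000,2000,500,200,2000,1000
1,6,100,2000,2000,100,300,2000,1000
1,7,9999,9999,0,0,2000,9999,9999
1,8,9999,9999,0,1000,400,9999,9999
1,9,80,2500,300,0,1000,2500,1000
1,10,100,2000,150,220,180,2000,1000
1,11,150,4000,200,400,200,4000,1000
2,1,9999,9999,100,400,300,9999,9999
2,2,9999,9000,150,200,150,9000,400
2,3,9999,9000,100,350,200,9000,400
2,4,9999,9000,1500,500,200,9000,400
2,5,250,4000,2000,500,200,2000,1000
2,6,500,8000,1700,100,300,4000,600
2,7,9999,9999,0,0,2000,9999,9999
2,8,9999,9999,0,1000,400,9999,9999
2,9,9999,9000,200,0,800,9000,400
2,10,9999,9000,120,300,180,9000,400
2,11,9999,9000,140,400,200,9000,400
3,1,9999,9999,100,400,300,9999,9999
3,2,9999,9999,10,150,150,9999,1000
3,3,9999,9000,100,350,200,9000,400
3,4,9999,9000,1000,500,200,9000,400
3,5,250,4000,2000,500,200,3000,1000
3,6,500,8000,1500,200,300,6000,600
3,7,9999,9999,0,0,2000,9999,9999
3,8,9999,9999,0,1000,400,9999,9999
3,9,9999,9000,100,0,1000,9000,800
3,10,9999,9000,50,200,180,9000,600
3,11,9999,9000,120,400,200,9000,600
4,1,9999,9999,100,100,600,9999,9999
4,2,9999,9999,10,100,3500,9999,1000
4,3,9999,9999,10,100,3500,9999,1000
4,4,9999,9999,1000,100,3500,9000,400
4,5,400,6000,2000,100,3500,200,1500
4,6,800,9000,1500,100,3500,400,600
4,7,9999,9999,0,0,2000,9999,9999
4,8,9999,9999,0,1000,400,9999,9999
4,9,9999,9000,50,100,3500,9000,800
4,10,9999,9000,10,100,3500,9999,1000
4,11,9999,9000,50,50,3500,9000,800
5,1,9999,9999,100,500,300,9999,9999
5,2,120,4000,50,150,150,4000,1000
5,3,240,4000,80,350,200,4000,500
5,4,140,4000,1200,500,200,4000,500
5,5,250,2000,2000,500,200,2000,1500
5,6,190,3000,1500,200,300,3000,700
5,7,9999,9999,0,0,2000,9999,9999
5,8,9999,9999,0,1000,400,9999,9999
5,9,160,4000,200,0,1000,4000,600
5,10,200,4000,60,250,180,4000,800
5,11,300,8000,120,400,200,8000,800
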