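respondent_id,scenario,task,alt,form,size,color,copay_pln,chosen,female,age,chronic_meds
1,chronic,1,1,round_tablet,small,blue,20,0,1,54.88234839057972,0
1,chronic,1,2,long_tablet,small,yellow,20,1,1,54.88234839057972,0
1,chronic,2,1,round_tablet,small,yellow,5,1,1,54.88234839057972,0
1,chronic,2,2,round_tablet,large,white,10,0,1,54.88234839057972,0
1,chronic,3,1,round_tablet,medium,white,10,1,1,54.88234839057972,0
1,chronic,3,2,capsule,large,red,15,0,1,54.88234839057972,0
1,chronic,4,1,capsule,medium,white,15,1,1,54.88234839057972,0
1,chronic,4,2,long_tablet,medium,white,20,0,1,54.88234839057972,0
1,short_term,1,1,long_tablet,small,blue,20,0,1,54.88234839057972,0
1,short_term,1,2,long_tablet,medium,white,10,1,1,54.88234839057972,0
1,short_term,2,1,round_tablet,small,white,20,0,1,54.88234839057972,0
1,short_term,2,2,capsule,small,yellow,5,1,1,54.88234839057972,0
1,short_term,3,1,capsule,medium,red,15,0,1,54.88234839057972,0
1,short_term,3,2,capsule,small,yellow,15,1,1,54.88234839057972,0
1,short_term,4,1,long_tablet,large,white,20,0,1,54.88234839057972,0
1,short_term,4,2,capsule,small,yellow,15,1,1,54.88234839057972,0
2,chronic,1,1,round_tablet,small,blue,20,0,1,44.78122840915732,0
2,chronic,1,2,long_tablet,small,yellow,20,1,1,44.78122840915732,0
2,chronic,2,1,round_tablet,small,yellow,5,1,1,44.78122840915732,0
2,chronic,2,2,round_tablet,large,white,10,0,1,44.78122840915732,0
2,chronic,3,1,round_tablet,medium,white,10,1,1,44.78122840915732,0
2,chronic,3,2,capsule,large,red,15,0,1,44.78122840915732,0
2,chronic,4,1,capsule,medium,white,15,1,1,44.78122840915732,0
2,chronic,4,2,long_tablet,medium,white,20,0,1,44.78122840915732,0
2,short_term,1,1,long_tablet,small,blue,20,0,1,44.78122840915732,0
2,short_term,1,2,long_tablet,medium,white,10,1,1,44.78122840915732,0
2,short_term,2,1,round_tablet,small,white,20,0,1,44.78122840915732,0
2,short_term,2,2,capsule,small,yellow,5,1,1,44.78122840915732,0
2,short_term,3,1,capsule,medium,red,15,0,1,44.78122840915732,0
2,short_term,3,2,capsule,small,yellow,15,1,1,44.78122840915732,0
2,short_term,4,1,long_tablet,large,white,20,0,1,44.78122840915732,0
2,short_term,4,2,capsule,small,yellow,15,1,1,44.78122840915732,0
3,chronic,1,1,round_tablet,small,blue,20,0,0,45.436370387912056,0
3,chronic,1,2,long_tablet,small,yellow,20,1,0,45.436370387912056,0
3,chronic,2,1,round_tablet,small,yellow,5,1,0,45.436370387912056,0
3,chronic,2,2,round_tablet,large,white,10,0,0,45.436370387912056,0
3,chronic,3,1,round_tablet,medium,white,10,0,0,45.436370387912056,0
3,chronic,3,2,capsule,large,red,15,1,0,45.436370387912056,0
3,chronic,4,1,capsule,medium,white,15,1,0,45.436370387912056,0
3,chronic,4,2,long_tablet,medium,white,20,0,0,45.436370387912056,0
3,short_term,1,1,long_tablet,small,blue,20,0,0,45.436370387912056,0
3,short_term,1,2,long_tablet,medium,white,10,1,0,45.436370387912056,0
3,short_term,2,1,round_tablet,small,white,20,0,0,45.436370387912056,0
3,short_term,2,2,capsule,small,yellow,5,1,0,45.436370387912056,0
3,short_term,3,1,capsule,medium,red,15,0,0,45.436370387912056,0
3,short_term,3,2,capsule,small,yellow,15,1,0,45.436370387912056,0
3,short_term,4,1,long_tablet,large,white,20,0,0,45.436370387912056,0
3,short_term,4,2,capsule,small,yellow,15,1,0,45.436370387912056,0
4,chronic,1,1,round_tablet,small,blue,20,0,0,42.831317655700445,1
4,chronic,1,2,long_tablet,small,yellow,20,1,0,42.831317655700445,1
4,chronic,2,1,round_tablet,small,yellow,5,1,0,42.831317655700445,1
4,chronic,2,2,round_tablet,large,white,10,0,0,42.831317655700445,1
4,chronic,3,1,round_tablet,medium,white,10,1,0,42.831317655700445,1
4,chronic,3,2,capsule,large,red,15,0,0,42.831317655700445,1
4,chronic,4,1,capsule,medium,white,15,1,0,42.831317655700445,1
4,chronic,4,2,long_tablet,medium,white,20,0,0,42.831317655700445,1
4,short_term,1,1,long_tablet,small,blue,20,0,0,42.831317655700445,1
4,short_term,1,2,long_tablet,medium,white,10,1,0,42.831317655700445,1
4,short_term,2,1,round_tablet,small,white,20,0,0,42.831317655700445,1
4,short_term,2,2,capsule,small,yellow,5,1,0,42.831317655700445,1
4,short_term,3,1,capsule,medium,red,15,0,0,42.831317655700445,1
4,short_term,3,2,capsule,small,yellow,15,1,0,42.831317655700445,1
4,short_term,4,1,long_tablet,large,white,20,0,0,42.831317655700445,1
4,short_term,4,2,capsule,small,yellow,15,1,0,42.831317655700445,1
5,chronic,1,1,round_tablet,small,blue,20,1,1,53.192832480067764,1
5,chronic,1,2,long_tablet,small,yellow,20,0,1,53.192832480067764,1
5,chronic,2,1,round_tablet,small,yellow,5,1,1,53.192832480067764,1
5,chronic,2,2,round_tablet,large,white,10,0,1,53.192832480067764,1
5,chronic,3,1,round_tablet,medium,white,10,1,1,53.192832480067764,1
5,chronic,3,2,capsule,large,red,15,0,1,53.192832480067764,1
5,chronic,4,1,capsule,medium,white,15,1,1,53.192832480067764,1
5,chronic,4,2,long_tablet,medium,white,20,0,1,53.192832480067764,1
5,short_term,1,1,long_tablet,small,blue,20,0,1,53.192832480067764,1
5,short_term,1,2,long_tablet,medium,white,10,1,1,53.192832480067764,1
5,short_term,2,1,round_tablet,small,white,20,0,1,53.192832480067764,1
5,short_term,2,2,capsule,small,yellow,5,1,1,53.192832480067764,1
5,short_term,3,1,capsule,medium,red,15,0,1,53.192832480067764,1
5,short_term,3,2,capsule,small,yellow,15,1,1,53.192832480067764,1
5,short_term,4,1,long_tablet,large,white,20,0,1,53.192832480067764,1
5,short_term,4,2,capsule,small,yellow,15,1,1,53.192832480067764,1
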