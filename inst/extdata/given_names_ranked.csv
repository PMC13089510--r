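name,rank
James,1
Mary,2
Robert,3
Patricia,4
John,5
Jennifer,6
Michael,7
Linda,8
David,9
Elizabeth,10
William,11
Barbara,12
Richard,13
Susan,14
Joseph,15
Jessica,16
Thomas,17
Sarah,18
Charles,19
Karen,20
Christopher,21
Lisa,22
Daniel,23
Nancy,24
Matthew,25
Betty,26
Anthony,27
Sandra,28
Mark,29
Margaret,30
Donald,31
Ashley,32
Steven,33
Kimberly,34
Andrew,35
Emily,36
Paul,37
Donna,38
Joshua,39
Michelle,40
Kenneth,41
Carol,42
Kevin,43
Amanda,44
Brian,45
Melissa,46
George,47
Deborah,48
Timothy,49
Stephanie,50
Ronald,51
Dorothy,52
Jason,53
Rebecca,54
Edward,55
Sharon,56
Jeffrey,57
Laura,58
Ryan,59
Cynthia,60
Jacob,61
Amy,62
Gary,63
Kathleen,64
Nicholas,65
Angela,66
Eric,67
Shirley,68
Jonathan,69
Brenda,70
Stephen,71
Emma,72
Larry,73
Anna,74
Justin,75
Pamela,76
Scott,77
Nicole,78
Brandon,79
Samantha,80
Benjamin,81
Katherine,82
Samuel,83
Christine,84
Gregory,85
Helen,86
Alexander,87
Debra,88
Patrick,89
Rachel,90
Frank,91
Carolyn,92
Raymond,93
Janet,94
Jack,95
Maria,96
Dennis,97
Catherine,98
Jerry,99
Heather,100
Tyler,101
Diane,102
Aaron,103
Olivia,104
Jose,105
Julie,106
Adam,107
Joyce,108
Nathan,109
Victoria,110
Henry,111
Ruth,112
Zachary,113
Virginia,114
Douglas,115
Lauren,116
Peter,117
Kelly,118
Kyle,119
Christina,120
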